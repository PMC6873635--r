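# Per-sample orchestration: merge reads, call every locus (independently,
# optionally in parallel), assign the ST, write reports and novel alleles.

#' Type one sample from a read set
#'
#' Loci are processed independently (forked workers when `workers > 1`);
#' results are identical for any worker count. A fault inside one locus marks
#' that locus `no_output` and never blanks the others.
#'
#' @param reads a [read_set()], or character vector of FASTQ paths (merged
#'   with [merge_fastq()], pairing disregarded).
#' @param db an [mlst_db()].
#' @param profiles an [mlst_profiles()].
#' @param params see [typing_params()].
#' @param workers parallel workers for the per-locus loop.
#' @param sample_id sample identifier.
#' @return an `st_call` object; see [report_row()] for the TSV row.
#' @export
type_sample <- function(reads, db, profiles, params = typing_params(),
                        workers = 1L, sample_id = "sample") {
  if (is.character(reads)) reads <- merge_fastq(reads)
  one <- function(locus_name) {
    tryCatch(call_locus(reads, db$loci[[locus_name]], params),
             error = function(e)
               allele_call(locus_name, "no_output",
                           note = conditionMessage(e)))
  }
  calls <- if (workers > 1L) {
    parallel::mclapply(db$schema, one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(db$schema, one)
  }
  names(calls) <- db$schema
  # a worker that died entirely surfaces as a try-error object
  for (nm in names(calls)) {
    if (!inherits(calls[[nm]], "allele_call"))
      calls[[nm]] <- allele_call(nm, "no_output", note = "worker failure")
  }
  assign_st(calls, profiles, sample_id = sample_id)
}

# resolve FASTQ files for a sample id inside a directory
sample_fastqs <- function(reads_dir, sample_id) {
  files <- list.files(reads_dir, full.names = TRUE,
                      pattern = "\\.fastq(\\.gz)?$")
  hit <- startsWith(basename(files), sample_id)
  files[hit]
}

#' Type one sample from files on disk
#'
#' Resolves `<sample_id>*.fastq[.gz]` inside `reads_dir`, loads the allele
#' database and profile table, types the sample, appends the report row and
#' writes any novel alleles under `out_dir/new_alleles/`.
#'
#' @param reads_dir directory of FASTQ files.
#' @param db_dir directory of per-locus allele FASTA files.
#' @param profile_path profile TSV.
#' @param sample_id sample identifier (file prefix).
#' @param out_dir output directory (created if needed); `NULL` writes nothing.
#' @param params,workers see [type_sample()].
#' @return the `st_call`, invisibly; the report row is attached as attribute
#'   `report`.
#' @export
run_sample <- function(reads_dir, db_dir, profile_path, sample_id,
                       out_dir = NULL, params = typing_params(),
                       workers = 1L) {
  profiles <- read_profile_table(profile_path)
  db <- read_allele_db(db_dir, loci = profiles$schema)
  fq <- sample_fastqs(reads_dir, sample_id)
  if (length(fq) == 0L)
    stop_mlst("no FASTQ files for sample '", sample_id, "' in '",
              reads_dir, "'")
  st <- type_sample(fq, db, profiles, params, workers, sample_id)
  row <- report_row(st)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(row, file.path(out_dir, paste0(sample_id, ".tsv")))
    write_new_alleles(st, out_dir, sample_id)
  }
  attr(st, "report") <- row
  invisible(st)
}

#' Write a typing report TSV
#'
#' @param report data frame of [report_row()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the leave-correct-allele-out benchmark
#'
#' Every sample is typed twice: against the full database (correct-allele
#' capability) and against a per-sample database lacking the sample's true
#' alleles (new-allele capability). Returns the two prediction tables, both
#' sets of calls, and allele- and ST-level metric summaries.
#'
#' @param samples named list of [read_set()]s (or a list from
#'   [simulate_benchmark()]`$samples`).
#' @param db,profiles reference database and profile table.
#' @param truth truth data frame (`sample`, locus columns, `ST`).
#' @param params,workers see [type_sample()].
#' @param reduced run the leave-one-out pass (default `TRUE`).
#' @return list: `preds_full`, `preds_reduced`, `calls_full`, `calls_reduced`,
#'   `metrics` (allele level), `st_metrics_full`, `st_metrics_reduced`.
#' @export
run_benchmark <- function(samples, db, profiles, truth,
                          params = typing_params(), workers = 1L,
                          reduced = TRUE) {
  if (!is.null(samples[[1]]$reads)) {
    named <- lapply(samples, `[[`, "reads")
    names(named) <- vapply(samples, `[[`, character(1), "sample_id")
    samples <- named
  }
  unknown <- setdiff(names(samples), truth$sample)
  if (length(unknown))
    stop_mlst("truth table lacks sample(s): ", paste(unknown, collapse = ", "))
  type_all <- function(get_db) {
    calls <- lapply(names(samples), function(sid)
      type_sample(samples[[sid]], get_db(sid), profiles, params, workers,
                  sample_id = sid))
    names(calls) <- names(samples)
    preds <- do.call(rbind, lapply(calls, report_row))
    rownames(preds) <- NULL
    list(calls = calls, preds = preds)
  }
  full <- type_all(function(sid) db)
  red <- NULL
  if (reduced) {
    red <- type_all(function(sid) {
      tr <- truth[truth$sample == sid, profiles$schema, drop = FALSE]
      remove_alleles(db, setNames(as.integer(tr[1, ]), profiles$schema))
    })
  }
  list(preds_full = full$preds,
       preds_reduced = if (reduced) red$preds,
       calls_full = full$calls,
       calls_reduced = if (reduced) red$calls,
       metrics = allele_metrics(full$preds,
                                if (reduced) red$preds, truth),
       st_metrics_full = st_metrics(full$preds, truth),
       st_metrics_reduced = if (reduced) st_metrics(red$preds, truth))
}
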