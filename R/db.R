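# Allele reference databases and ST profile tables (PubMLST file conventions).

#' Construct a locus of reference alleles
#'
#' A locus holds the known allele sequences of one MLST housekeeping gene,
#' each identified by a positive integer (PubMLST numbering).
#'
#' @param name locus name (e.g. `"adk"`).
#' @param allele_id integer vector of allele numbers.
#' @param sequence character vector of DNA sequences (upper-cased on input).
#' @return an object of class `mlst_locus`.
#' @export
mlst_locus <- function(name, allele_id, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            length(allele_id) == length(sequence))
  allele_id <- as.integer(allele_id)
  if (anyNA(allele_id) || any(allele_id < 1L))
    stop_mlst("allele ids must be positive integers")
  if (anyDuplicated(allele_id))
    stop_mlst("duplicate allele id(s) in locus '", name, "': ",
              paste(unique(allele_id[duplicated(allele_id)]), collapse = ", "))
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) < 1L))
    stop_mlst("empty allele sequence in locus '", name, "'")
  ord <- order(allele_id)
  structure(list(name = name,
                 allele_id = allele_id[ord],
                 sequence = sequence[ord]),
            class = "mlst_locus")
}

#' @export
print.mlst_locus <- function(x, ...) {
  cat(sprintf("<mlst_locus> %s: %d allele(s), lengths %d-%d bp\n",
              x$name, length(x$allele_id),
              min(nchar(x$sequence)), max(nchar(x$sequence))))
  invisible(x)
}

#' @export
length.mlst_locus <- function(x) length(x$allele_id)

#' Construct an allele database
#'
#' @param loci list of [mlst_locus()] objects.
#' @param schema character vector of locus names giving the profile-table
#'   column order; defaults to the order of `loci`.
#' @return an object of class `mlst_db`.
#' @export
mlst_db <- function(loci, schema = NULL) {
  names(loci) <- vapply(loci, function(l) l$name, character(1))
  if (is.null(schema)) schema <- names(loci)
  if (!setequal(schema, names(loci)) || length(schema) != length(loci))
    stop_mlst("schema must name exactly the loci present")
  structure(list(loci = loci[schema], schema = schema), class = "mlst_db")
}

#' @export
print.mlst_db <- function(x, ...) {
  cat(sprintf("<mlst_db> %d loci: %s\n", length(x$schema),
              paste(x$schema, collapse = ", ")))
  for (l in x$loci) cat(sprintf("  %-12s %4d alleles\n", l$name, length(l)))
  invisible(x)
}

parse_allele_headers <- function(headers, path) {
  id_tok <- sub("^.*_", "", headers)
  bad <- !grepl("^[0-9]+$", id_tok) | !grepl("_", headers)
  if (any(bad))
    stop_mlst("unparseable allele header(s) in '", path, "' at record(s) ",
              paste(which(bad), collapse = ", "),
              ": expected '<locus>_<number>', got e.g. '",
              headers[which(bad)[1]], "'")
  list(locus = sub("_[0-9]+$", "", headers), id = as.integer(id_tok))
}

#' Read a PubMLST allele FASTA file
#'
#' Headers follow the PubMLST convention `<locus>_<allele-number>` (e.g.
#' `adk_3`); the allele number is the integer after the final underscore, so
#' locus names containing underscores remain parseable. Sequences are
#' upper-cased. Records containing characters outside A/C/G/T are rejected by
#' default (exact matching is undefined on ambiguity codes) or silently
#' dropped with `on_ambiguity = "drop"`.
#'
#' @param path FASTA file.
#' @param locus_name locus name; defaults to the file name without extension.
#' @param on_ambiguity `"error"` (default) or `"drop"`.
#' @return an [mlst_locus()].
#' @export
read_allele_fasta <- function(path, locus_name = NULL,
                              on_ambiguity = c("error", "drop")) {
  on_ambiguity <- match.arg(on_ambiguity)
  if (!file.exists(path)) stop_mlst("no such file: '", path, "'")
  if (is.null(locus_name))
    locus_name <- tools::file_path_sans_ext(basename(path), compression = TRUE)
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop_mlst("no alleles in '", path, "'")
  headers <- sub("\\s.*$", "", names(seqs))
  parsed <- parse_allele_headers(headers, path)
  sequence <- toupper(as.character(seqs))
  amb <- grepl("[^ACGT]", sequence)
  if (any(amb)) {
    if (on_ambiguity == "error")
      stop_mlst("non-ACGT character(s) in '", path, "' record(s) ",
                paste(which(amb), collapse = ", "))
    parsed$id <- parsed$id[!amb]
    sequence <- sequence[!amb]
    if (length(sequence) == 0L) stop_mlst("no alleles in '", path, "'")
  }
  mlst_locus(locus_name, parsed$id, sequence)
}

#' Read a directory of per-locus allele FASTA files
#'
#' One FASTA per locus, file name stem = locus name (PubMLST layout).
#'
#' @param dir directory containing `<locus>.fasta`/`.fa`/`.tfa` files.
#' @param loci optional locus names (and schema order); defaults to all FASTA
#'   files found, alphabetically.
#' @inheritParams read_allele_fasta
#' @return an [mlst_db()].
#' @export
read_allele_db <- function(dir, loci = NULL, on_ambiguity = c("error", "drop")) {
  on_ambiguity <- match.arg(on_ambiguity)
  files <- list.files(dir, pattern = "\\.(fa|fasta|tfa)(\\.gz)?$",
                      full.names = TRUE)
  stems <- tools::file_path_sans_ext(basename(files), compression = TRUE)
  if (is.null(loci)) {
    ord <- order(stems)
    files <- files[ord]; stems <- stems[ord]
  } else {
    miss <- setdiff(loci, stems)
    if (length(miss))
      stop_mlst("missing allele FASTA for locus/loci: ",
                paste(miss, collapse = ", "))
    files <- files[match(loci, stems)]
    stems <- loci
  }
  if (length(files) == 0L) stop_mlst("no allele FASTA files in '", dir, "'")
  mlst_db(Map(read_allele_fasta, files, stems,
              MoreArgs = list(on_ambiguity = on_ambiguity)))
}

#' Write a locus to FASTA with PubMLST headers
#'
#' @param locus an [mlst_locus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(locus, path) {
  set <- Biostrings::DNAStringSet(locus$sequence)
  names(set) <- paste0(locus$name, "_", locus$allele_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# columns PubMLST appends after the allele columns
.profile_extras <- c("clonal_complex", "species", "CC", "Lineage", "cc",
                     "mlst_clade", "comments")

#' Read an ST profile definition table
#'
#' Tab-separated, header `ST<TAB>locus1...locusL`, one row per sequence type.
#' Trailing non-allele columns (e.g. `clonal_complex`) are ignored. Each
#' allele-number tuple must map to exactly one ST.
#'
#' @param path profile TSV.
#' @param loci optional character vector naming the locus columns; by default
#'   every integer-valued column after `ST` (up to the first known extra or
#'   non-integer column) is taken as a locus.
#' @return an object of class `mlst_profiles` with fields `schema`, `st`
#'   (integer vector) and `alleles` (integer matrix, one row per ST).
#' @export
read_profile_table <- function(path, loci = NULL) {
  if (!file.exists(path)) stop_mlst("no such file: '", path, "'")
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L || toupper(names(tab)[1]) != "ST")
    stop_mlst("profile table must start with an 'ST' column: '", path, "'")
  candidates <- names(tab)[-1L]
  if (is.null(loci)) {
    is_locus <- logical(length(candidates))
    for (i in seq_along(candidates)) {
      col <- tab[[candidates[i]]]
      if (candidates[i] %in% .profile_extras || !all(grepl("^[0-9]+$", col))) break
      is_locus[i] <- TRUE
    }
    loci <- candidates[is_locus]
    if (length(loci) == 0L)
      stop_mlst("no allele columns recognised in '", path, "'")
  } else {
    miss <- setdiff(loci, candidates)
    if (length(miss))
      stop_mlst("profile table lacks locus column(s): ",
                paste(miss, collapse = ", "))
  }
  st <- suppressWarnings(as.integer(tab$ST))
  if (anyNA(st)) stop_mlst("non-integer ST value(s) in '", path, "'")
  alleles <- matrix(NA_integer_, nrow(tab), length(loci),
                    dimnames = list(NULL, loci))
  for (l in loci) {
    v <- suppressWarnings(as.integer(tab[[l]]))
    if (anyNA(v))
      stop_mlst("non-integer allele number in column '", l, "' of '", path, "'")
    alleles[, l] <- v
  }
  mlst_profiles(loci, st, alleles)
}

#' Construct a profile table object
#'
#' @param schema ordered locus names.
#' @param st integer STs.
#' @param alleles integer matrix (rows = STs, columns = schema).
#' @return an `mlst_profiles` object.
#' @export
mlst_profiles <- function(schema, st, alleles) {
  st <- as.integer(st)
  alleles <- as.matrix(alleles)
  colnames(alleles) <- schema
  storage.mode(alleles) <- "integer"
  stopifnot(length(st) == nrow(alleles))
  key <- apply(alleles, 1L, paste, collapse = "-")
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- key %in% key[dup]
    if (any(tapply(st[clash], key[clash], function(x) length(unique(x))) > 1L))
      stop_mlst("profile table maps the same allele combination to different STs")
    st <- st[!dup]; alleles <- alleles[!dup, , drop = FALSE]; key <- key[!dup]
  }
  if (anyDuplicated(st))
    stop_mlst("duplicate ST with conflicting allele combinations: ",
              paste(unique(st[duplicated(st)]), collapse = ", "))
  structure(list(schema = schema, st = st, alleles = alleles,
                 key = setNames(st, key)),
            class = "mlst_profiles")
}

#' @export
print.mlst_profiles <- function(x, ...) {
  cat(sprintf("<mlst_profiles> %d STs over %d loci (%s)\n",
              length(x$st), length(x$schema), paste(x$schema, collapse = ", ")))
  invisible(x)
}

#' Remove alleles from a database
#'
#' Implements the leave-correct-allele-out construction used to measure new
#' allele detection: the returned database is identical to `db` except that,
#' for each named locus, the given allele is absent. `db` is not modified.
#'
#' @param db an [mlst_db()].
#' @param assignments named integer vector or list, locus name to allele id.
#' @return a new `mlst_db`.
#' @export
remove_alleles <- function(db, assignments) {
  assignments <- unlist(assignments)
  for (locus in names(assignments)) {
    if (!locus %in% db$schema)
      stop_mlst("no such locus in database: '", locus, "'")
    l <- db$loci[[locus]]
    id <- as.integer(assignments[[locus]])
    hit <- l$allele_id == id
    if (!any(hit))
      stop_mlst("allele ", id, " not present in locus '", locus, "'")
    db$loci[[locus]] <- structure(
      list(name = l$name, allele_id = l$allele_id[!hit],
           sequence = l$sequence[!hit]),
      class = "mlst_locus")
  }
  db
}

#' Validate an allele database
#'
#' Reports (rather than raises) integrity findings: duplicate sequences within
#' a locus, non-ACGT characters, empty loci.
#'
#' @param db an [mlst_db()].
#' @return a data frame with columns `locus`, `type`, `detail`; zero rows for
#'   a clean database.
#' @export
validate_db <- function(db) {
  out <- list()
  for (l in db$loci) {
    if (length(l) == 0L) {
      out[[length(out) + 1L]] <-
        data.frame(locus = l$name, type = "empty_locus", detail = "no alleles")
      next
    }
    dup <- duplicated(l$sequence) | duplicated(l$sequence, fromLast = TRUE)
    if (any(dup))
      out[[length(out) + 1L]] <- data.frame(
        locus = l$name, type = "duplicate_sequence",
        detail = paste("allele ids", paste(l$allele_id[dup], collapse = ",")))
    bad <- grepl("[^ACGT]", l$sequence)
    if (any(bad))
      out[[length(out) + 1L]] <- data.frame(
        locus = l$name, type = "non_acgt",
        detail = paste("allele ids", paste(l$allele_id[bad], collapse = ",")))
  }
  if (length(out) == 0L)
    return(data.frame(locus = character(), type = character(),
                      detail = character()))
  do.call(rbind, out)
}

locus_seq <- function(locus, id) locus$sequence[match(id, locus$allele_id)]
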