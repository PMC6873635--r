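# Sequence-type assignment: look up the tuple of per-locus allele calls in
# the profile table.

#' Assign a sequence type from per-locus allele calls
#'
#' All loci called exactly and the allele-number tuple present in the profile
#' table gives status `"known"` with the ST. All loci resolved (exact or new)
#' but any novel allele, or a tuple absent from the table, gives
#' `"novel_combination"`. Any low-coverage or no-output locus gives
#' `"incomplete"`.
#'
#' @param calls named list of `allele_call` objects covering every schema
#'   locus, or an unnamed list (names taken from the calls).
#' @param profiles an [mlst_profiles()].
#' @param sample_id sample identifier carried into the result.
#' @return an `st_call` object with fields `sample_id`, `locus_calls`,
#'   `st_status` and `st_id` (`NA` unless known).
#' @export
assign_st <- function(calls, profiles, sample_id = "sample") {
  if (is.null(names(calls)) || any(names(calls) == ""))
    names(calls) <- vapply(calls, `[[`, character(1), "locus_name")
  miss <- setdiff(profiles$schema, names(calls))
  if (length(miss))
    stop_mlst("missing call(s) for locus/loci: ", paste(miss, collapse = ", "))
  calls <- calls[profiles$schema]
  status <- vapply(calls, `[[`, character(1), "status")
  st_status <- if (any(status %in% c("low_coverage", "no_output"))) {
    "incomplete"
  } else if (any(status == "new")) {
    "novel_combination"
  } else {
    key <- paste(vapply(calls, `[[`, integer(1), "allele_id"), collapse = "-")
    if (!is.na(profiles$key[key])) "known" else "novel_combination"
  }
  st_id <- if (st_status == "known") {
    key <- paste(vapply(calls, `[[`, integer(1), "allele_id"), collapse = "-")
    unname(profiles$key[key])
  } else NA_integer_
  structure(list(sample_id = sample_id, locus_calls = calls,
                 st_status = st_status, st_id = st_id),
            class = "st_call")
}

# report vocabulary: allele number, "New?", "low coverage", "" (no output)
call_label <- function(call) {
  switch(call$status,
         exact = as.character(call$allele_id),
         new = "New?",
         low_coverage = "low coverage",
         no_output = "")
}

st_label <- function(x) {
  switch(x$st_status,
         known = as.character(x$st_id),
         novel_combination = "new",
         incomplete = "ND")
}

#' @export
print.st_call <- function(x, ...) {
  cat(sprintf("<st_call> %s: ST %s (%s)\n", x$sample_id, st_label(x),
              x$st_status))
  for (cl in x$locus_calls)
    cat(sprintf("  %-12s %s\n", cl$locus_name, call_label(cl)))
  invisible(x)
}

#' One report row for a typed sample
#'
#' @param x an `st_call`.
#' @return a one-row data frame: `sample`, one column per locus (allele
#'   number, `New?` or `low coverage`), and `ST` (number, `new` or `ND`).
#' @export
report_row <- function(x) {
  row <- c(list(sample = x$sample_id),
           lapply(x$locus_calls, call_label),
           list(ST = st_label(x)))
  as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
}
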