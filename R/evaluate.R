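# Benchmark metrics: percentage of no-output, capability to identify correct
# alleles, capability to identify new alleles (leave-correct-allele-out
# protocol), at allele and ST level.
#
# Label vocabulary accepted in prediction tables:
#   "7"       allele number
#   "7*"      starred allele number (third-party tools flagging an imperfect
#             best hit; interpreted under high/low stringency)
#   "New?"    novel-allele flag
#   "", NA, "low coverage", "ND"   blank / no output
#
# Blanks stay in the denominator of both capabilities (a blank is a miss);
# low-coverage labels are treated as blanks since they name no allele and
# flag no novel one.

label_type <- function(x) {
  x <- ifelse(is.na(x), "", trimws(as.character(x)))
  type <- rep("blank", length(x))
  type[grepl("^[0-9]+$", x)] <- "allele"
  type[grepl("^[0-9]+\\*$", x)] <- "starred"
  type[x %in% c("New?", "new", "New")] <- "new"
  type
}

label_id <- function(x) {
  x <- ifelse(is.na(x), "", trimws(as.character(x)))
  suppressWarnings(as.integer(sub("\\*$", "", x)))
}

locus_columns <- function(preds, truth = NULL) {
  loci <- setdiff(names(preds), c("sample", "ST"))
  if (!is.null(truth)) loci <- intersect(loci, names(truth))
  if (length(loci) == 0L) stop_mlst("no locus columns found")
  loci
}

align_truth <- function(preds, truth) {
  i <- match(preds$sample, truth$sample)
  if (anyNA(i))
    stop_mlst("truth table lacks sample(s): ",
              paste(preds$sample[is.na(i)], collapse = ", "))
  truth[i, , drop = FALSE]
}

label_matrix <- function(tab, loci) {
  m <- as.matrix(tab[, loci, drop = FALSE])
  m[] <- as.character(m)
  m
}

#' Percentage of no-output
#'
#' Fraction of per-locus labels that are blank (empty, `NA`, `low coverage`).
#'
#' @param preds prediction data frame: `sample`, one column per locus,
#'   optionally `ST`.
#' @return fraction in \[0, 1\].
#' @export
pct_no_output <- function(preds) {
  loci <- locus_columns(preds)
  m <- label_matrix(preds, loci)
  if (length(m) == 0L) stop_mlst("empty prediction set")
  mean(label_type(m) == "blank")
}

#' Capability to identify correct alleles
#'
#' Fraction of labels equal to the true allele number. Starred labels count
#' as hits only under low stringency (the star is ignored); under high
#' stringency a starred correct number is a miss. Blanks and novel-allele
#' flags are misses. Denominator = all labels (samples x loci).
#'
#' @param preds prediction data frame (`sample` + locus columns).
#' @param truth truth data frame (`sample` + locus columns, integer alleles).
#' @param stringency `"high"` or `"low"`.
#' @return fraction in \[0, 1\].
#' @export
capability_correct <- function(preds, truth, stringency = c("high", "low")) {
  stringency <- match.arg(stringency)
  loci <- locus_columns(preds, truth)
  tr <- align_truth(preds, truth)
  p <- label_matrix(preds, loci)
  t_ <- label_matrix(tr, loci)
  if (length(p) == 0L) stop_mlst("empty prediction set")
  type <- label_type(p)
  id <- label_id(p)
  tid <- suppressWarnings(as.integer(t_))
  hit <- type == "allele" & id == tid
  if (stringency == "low") hit <- hit | (type == "starred" & id == tid)
  mean(hit, na.rm = FALSE)
}

#' Capability to identify new alleles
#'
#' For predictions made against a reference database from which each sample's
#' true alleles were removed: fraction of labels flagging a novel allele.
#' `New?` always counts; starred labels count as new-allele flags under high
#' stringency only. Labels naming any reference allele, and blanks, are
#' misses. Denominator = all labels.
#'
#' @param preds predictions produced against the reduced database.
#' @param truth truth data frame (used for alignment and denominators).
#' @param stringency `"high"` or `"low"`.
#' @return fraction in \[0, 1\].
#' @export
capability_new <- function(preds, truth, stringency = c("high", "low")) {
  stringency <- match.arg(stringency)
  loci <- locus_columns(preds, truth)
  align_truth(preds, truth)  # validates sample alignment
  p <- label_matrix(preds, loci)
  if (length(p) == 0L) stop_mlst("empty prediction set")
  type <- label_type(p)
  hit <- type == "new"
  if (stringency == "high") hit <- hit | type == "starred"
  mean(hit)
}

#' ST-level metrics
#'
#' The same three fractions computed over the per-sample ST labels: a correct
#' ST requires the full allele combination to resolve to the true ST; the
#' new-ST capability counts samples whose predicted ST is `new`.
#'
#' @param preds prediction data frame with an `ST` column (number, `new`,
#'   `ND`).
#' @param truth truth data frame with an `ST` column.
#' @return an `mlst_metrics` object (fields `pct_no_output`,
#'   `capability_correct`, `capability_new`, `n`).
#' @export
st_metrics <- function(preds, truth) {
  if (is.null(preds$ST) || is.null(truth$ST))
    stop_mlst("both tables need an ST column")
  tr <- align_truth(preds, truth)
  p <- trimws(as.character(preds$ST))
  blank <- is.na(preds$ST) | p %in% c("", "ND", "NA")
  correct <- !blank & p == trimws(as.character(tr$ST))
  newst <- !blank & p %in% c("new", "New", "NEW")
  mlst_metrics(mean(blank), mean(correct), mean(newst), length(p),
               level = "ST")
}

mlst_metrics <- function(pct_no_output, capability_correct, capability_new,
                         n, level = "allele") {
  structure(list(pct_no_output = pct_no_output,
                 capability_correct = capability_correct,
                 capability_new = capability_new,
                 n = n, level = level),
            class = "mlst_metrics")
}

#' @export
print.mlst_metrics <- function(x, ...) {
  cat(sprintf("<mlst_metrics> (%s level, n = %d)\n", x$level, x$n))
  cat(sprintf("  no-output:            %5.1f%%\n", 100 * x$pct_no_output))
  if (!is.na(x$capability_correct))
    cat(sprintf("  correct identified:   %5.1f%%\n",
                100 * x$capability_correct))
  if (!is.na(x$capability_new))
    cat(sprintf("  new identified:       %5.1f%%\n", 100 * x$capability_new))
  invisible(x)
}

#' Allele-level metrics summary
#'
#' Convenience wrapper bundling the three allele-level fractions, with the
#' correct-allele capability computed from the full-database run and the
#' new-allele capability from the leave-correct-allele-out run.
#'
#' @param preds_full predictions against the full database.
#' @param preds_reduced predictions against the per-sample reduced databases
#'   (may be `NULL`).
#' @param truth truth table.
#' @param stringency star interpretation, see [capability_correct()].
#' @return an `mlst_metrics` object.
#' @export
allele_metrics <- function(preds_full, preds_reduced = NULL, truth,
                           stringency = "high") {
  mlst_metrics(
    pct_no_output(preds_full),
    capability_correct(preds_full, truth, stringency),
    if (is.null(preds_reduced)) NA_real_
    else capability_new(preds_reduced, truth, stringency),
    length(locus_columns(preds_full, truth)) * nrow(preds_full))
}
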