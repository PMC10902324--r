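# Patient cohort: severity labels and per-patient variant gene lists.

.SEVERITY_LEVELS <- c("severe", "not_severe")
.FINE_LEVELS <- c("mild", "intermediate", "severe")

#' Construct a patient cohort
#'
#' @param id Character vector of unique patient identifiers.
#' @param severity Character vector: `"severe"` or `"not_severe"` per patient.
#' @param compound_het List of character vectors: genes carrying compound
#'   heterozygous variants per patient.
#' @param cnv List of character vectors: genes with copy-number variants per
#'   patient.
#' @param fine_label Optional finer severity: `"mild"`, `"intermediate"` or
#'   `"severe"`; must be consistent with `severity` (mild/intermediate imply
#'   not_severe). `NA` allowed.
#' @param treatment Optional logical vector (e.g. on pharmacological
#'   treatment); `NA` allowed.
#' @param clinical Optional data frame of logical clinical variables, one row
#'   per patient.
#' @return An object of class `ml_cohort`.
#' @export
ml_cohort <- function(id, severity, compound_het = NULL, cnv = NULL,
                      fine_label = NULL, treatment = NULL, clinical = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate patient ids", call. = FALSE)
  severity <- as.character(severity)
  if (length(severity) != n || anyNA(severity) || !all(severity %in% .SEVERITY_LEVELS))
    stop(sprintf("every patient needs a severity label; accepted tokens: %s",
                 paste(.SEVERITY_LEVELS, collapse = ", ")), call. = FALSE)
  norm_lists <- function(x, what) {
    if (is.null(x)) x <- rep(list(character(0)), n)
    if (!is.list(x) || length(x) != n)
      stop(sprintf("`%s` must be a list of gene vectors, one per patient", what),
           call. = FALSE)
    lapply(x, function(g) if (length(g)) sort(unique(.check_gene_ids(g, what))) else character(0))
  }
  compound_het <- norm_lists(compound_het, "compound_het")
  cnv <- norm_lists(cnv, "cnv")
  if (!is.null(fine_label)) {
    fine_label <- as.character(fine_label)
    stopifnot(length(fine_label) == n)
    known <- !is.na(fine_label)
    if (any(known & !fine_label %in% .FINE_LEVELS))
      stop(sprintf("fine labels must be one of: %s", paste(.FINE_LEVELS, collapse = ", ")),
           call. = FALSE)
    implied <- ifelse(fine_label == "severe", "severe", "not_severe")
    if (any(known & implied != severity))
      stop("fine label inconsistent with severity (mild/intermediate imply not_severe)",
           call. = FALSE)
  } else fine_label <- rep(NA_character_, n)
  if (!is.null(treatment)) {
    treatment <- as.logical(treatment)
    stopifnot(length(treatment) == n)
  } else treatment <- rep(NA, n)
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    stopifnot(nrow(clinical) == n)
    clinical[] <- lapply(clinical, as.logical)
  }
  structure(list(id = id, severity = severity, fine_label = fine_label,
                 treatment = treatment, compound_het = compound_het, cnv = cnv,
                 clinical = clinical),
            class = "ml_cohort")
}

#' @export
print.ml_cohort <- function(x, ...) {
  cat(sprintf("<ml_cohort>  %d patients (%d severe / %d not severe)\n",
              length(x$id), sum(x$severity == "severe"),
              sum(x$severity == "not_severe")))
  cat(sprintf("  genes per patient: compound-het median %g, CNV median %g\n",
              stats::median(lengths(x$compound_het)), stats::median(lengths(x$cnv))))
  if (!is.null(x$clinical))
    cat("  clinical variables:", paste(names(x$clinical), collapse = ", "), "\n")
  invisible(x)
}

# All variant genes of one patient (both classes).
.patient_genes <- function(cohort) {
  mapply(function(a, b) unique(c(a, b)), cohort$compound_het, cohort$cnv,
         SIMPLIFY = FALSE)
}

# Private-union computation reused verbatim by the label-shuffle null.
.group_private <- function(gene_lists, severe_mask) {
  severe_union <- sort(unique(unlist(gene_lists[severe_mask], use.names = FALSE)))
  not_union <- sort(unique(unlist(gene_lists[!severe_mask], use.names = FALSE)))
  list(severe_union = severe_union,
       not_severe_union = not_union,
       severe_private = setdiff(severe_union, not_union),
       not_severe_private = setdiff(not_union, severe_union))
}

#' Group-specific gene sets of a cohort
#'
#' Builds the severity-group unions and group-private gene sets (genes seen in
#' at least one patient of a group and in no patient of the other), per
#' variant class and combined, plus the set of disease-linked genes over which
#' persistence modules are defined: known causal genes together with each
#' group's private variant genes.
#'
#' @param cohort An [ml_cohort].
#' @param causal Character vector of known causal genes.
#' @return An object of class `ml_genesets`: list with `severe_union`,
#'   `not_severe_union`, `severe_private`, `not_severe_private`, `linked`
#'   (causal and both unions), `severe_interest` / `not_severe_interest`
#'   (causal + group-private; the genes-of-interest used for group modules)
#'   and a `counts` table per variant class.
#' @export
build_group_gene_sets <- function(cohort, causal) {
  stopifnot(inherits(cohort, "ml_cohort"))
  causal <- sort(unique(.check_gene_ids(causal, "causal")))
  sev <- cohort$severity == "severe"
  if (!any(sev) || all(sev))
    stop("cohort must contain both severe and not-severe patients", call. = FALSE)
  all_g <- .group_private(.patient_genes(cohort), sev)
  ch <- .group_private(cohort$compound_het, sev)
  cn <- .group_private(cohort$cnv, sev)
  counts <- data.frame(
    class = c("compound_het", "cnv", "combined"),
    severe_union = c(length(ch$severe_union), length(cn$severe_union), length(all_g$severe_union)),
    severe_private = c(length(ch$severe_private), length(cn$severe_private), length(all_g$severe_private)),
    not_severe_union = c(length(ch$not_severe_union), length(cn$not_severe_union), length(all_g$not_severe_union)),
    not_severe_private = c(length(ch$not_severe_private), length(cn$not_severe_private), length(all_g$not_severe_private))
  )
  structure(c(all_g, list(
    causal = causal,
    linked = sort(unique(c(causal, all_g$severe_union, all_g$not_severe_union))),
    severe_interest = sort(unique(c(causal, all_g$severe_private))),
    not_severe_interest = sort(unique(c(causal, all_g$not_severe_private))),
    counts = counts
  )), class = "ml_genesets")
}

#' @export
print.ml_genesets <- function(x, ...) {
  cat("<ml_genesets>\n")
  cat(sprintf("  causal: %d | linked: %d\n", length(x$causal), length(x$linked)))
  cat(sprintf("  severe: union %d, private %d | not severe: union %d, private %d\n",
              length(x$severe_union), length(x$severe_private),
              length(x$not_severe_union), length(x$not_severe_private)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
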