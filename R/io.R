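# Readers and writers for the interchange formats: TSV edge lists, GMT
# gene-set collections, cohort tables, partitions and sweep archives. All
# writers emit lexicographically sorted records so outputs are diff-stable.

.read_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  readLines(path, warn = FALSE)
}

#' Read a layer from a TSV edge list
#'
#' Format: two or three tab-separated columns (`gene_a`, `gene_b`, optional
#' positive `weight`, default 1); lines starting with `#` and blank lines are
#' ignored. Repeated undirected edges are merged by summing weights (with a
#' warning); self-loops are rejected with the offending line number. Isolated
#' nodes can be supplied through an optional one-column node file.
#'
#' @param path Edge-list TSV path.
#' @param nodes_path Optional path to a one-identifier-per-line node file.
#' @param name Layer name (default: file name without extension).
#' @return An [ml_layer].
#' @export
read_layer <- function(path, nodes_path = NULL, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- .read_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L)
    stop(sprintf("no edges in %s", path), call. = FALSE)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stop(sprintf("malformed row at line %d of %s (expected 2 or 3 tab-separated fields)",
                 keep[which(nf < 2L | nf > 3L)[1L]], path), call. = FALSE)
  from <- vapply(parts, `[[`, character(1L), 1L)
  to <- vapply(parts, `[[`, character(1L), 2L)
  loop <- from == to
  if (any(loop))
    stop(sprintf("self-loop '%s' at line %d of %s", from[which(loop)[1L]],
                 keep[which(loop)[1L]], path), call. = FALSE)
  weight <- rep(1, length(from))
  has_w <- nf == 3L
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts[has_w], `[[`, character(1L), 3L)))
    if (anyNA(w))
      stop(sprintf("non-numeric weight at line %d of %s",
                   keep[has_w][which(is.na(w))[1L]], path), call. = FALSE)
    weight[has_w] <- w
  }
  nodes <- if (!is.null(nodes_path)) {
    nl <- trimws(.read_lines(nodes_path))
    nl[nzchar(nl) & !startsWith(nl, "#")]
  }
  ml_layer(data.frame(from = from, to = to, weight = weight,
                      stringsAsFactors = FALSE),
           nodes = nodes, name = name)
}

#' Write a layer as a TSV edge list
#' @param layer An [ml_layer].
#' @param path Output path.
#' @param nodes_path Optional path for the node list (written when given).
#' @export
write_layer <- function(layer, path, nodes_path = NULL) {
  stopifnot(inherits(layer, "ml_layer"))
  e <- layer$edges
  writeLines(sprintf("%s\t%s\t%g", e$from, e$to, e$weight), path)
  if (!is.null(nodes_path)) writeLines(layer$nodes, nodes_path)
  invisible(path)
}

#' Read a gene-set catalog in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then genes. Duplicate genes within a set are removed with a warning;
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return An [ml_catalog].
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop(sprintf("malformed GMT row at line %d of %s (need name, description, genes)",
                 keep[which(short)[1L]], path), call. = FALSE)
  nms <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nms))
    stop(sprintf("duplicate set name '%s' in %s", nms[duplicated(nms)][1L], path),
         call. = FALSE)
  descs <- vapply(parts, `[[`, character(1L), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  dups <- vapply(sets, anyDuplicated, integer(1L)) > 0L
  if (any(dups))
    warning(sprintf("duplicate genes within %d set(s) of %s removed",
                    sum(dups), path), call. = FALSE)
  names(sets) <- nms
  ml_catalog(sets, descs)
}

#' Write a gene-set catalog in GMT format
#' @param catalog An [ml_catalog].
#' @param path Output path.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "ml_catalog"))
  nms <- sort(names(catalog$sets))
  writeLines(vapply(nms, function(nm) {
    paste(c(nm, catalog$descriptions[[nm]], sort(catalog$sets[[nm]])),
          collapse = "\t")
  }, character(1L)), path)
  invisible(path)
}

#' Read a plain-text gene list (one identifier per line)
#' @param path File path; blank and `#` lines ignored.
#' @return Sorted character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(.read_lines(path))
  sort(unique(.check_gene_ids(x[nzchar(x) & !startsWith(x, "#")], basename(path))))
}

.parse_bool <- function(x, what, line) {
  out <- rep(NA, length(x))
  x <- trimws(x)
  out[x %in% c("1", "TRUE", "true", "T")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "F")] <- FALSE
  bad <- !(x %in% c("1", "TRUE", "true", "T", "0", "FALSE", "false", "F", "", "NA"))
  if (any(bad))
    stop(sprintf("invalid boolean '%s' for %s", x[bad][1L], what), call. = FALSE)
  out
}

#' Read a cohort TSV
#'
#' Tab-separated with header. Required columns: `patient_id`, `severity`
#' (exact tokens `severe` / `not_severe`), `fine_label` (`mild` /
#' `intermediate` / `severe` or empty), `treatment` (0/1/TRUE/FALSE or
#' empty), `compound_het` and `cnv` (semicolon-separated gene lists, empty
#' allowed). Any further columns are parsed as binary clinical variables.
#'
#' @param path Cohort TSV path.
#' @return An [ml_cohort].
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  req <- c("patient_id", "severity", "fine_label", "treatment", "compound_het", "cnv")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("cohort file %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- !df$severity %in% .SEVERITY_LEVELS
  if (any(bad))
    stop(sprintf("unknown severity '%s' for patient %s; accepted tokens: %s",
                 df$severity[bad][1L], df$patient_id[bad][1L],
                 paste(.SEVERITY_LEVELS, collapse = ", ")), call. = FALSE)
  split_genes <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                    function(g) g[nzchar(trimws(g))])
  fine <- trimws(df$fine_label)
  fine[fine == "" | fine == "NA"] <- NA_character_
  extra <- setdiff(names(df), req)
  clinical <- if (length(extra)) {
    cl <- lapply(extra, function(v) .parse_bool(df[[v]], v))
    names(cl) <- extra
    as.data.frame(cl, check.names = FALSE)
  }
  ml_cohort(id = df$patient_id, severity = df$severity,
            compound_het = split_genes(df$compound_het),
            cnv = split_genes(df$cnv),
            fine_label = fine,
            treatment = .parse_bool(df$treatment, "treatment"),
            clinical = clinical)
}

#' Write a cohort TSV
#' @param cohort An [ml_cohort].
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ml_cohort"))
  fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "1", "0"))
  df <- data.frame(
    patient_id = cohort$id,
    severity = cohort$severity,
    fine_label = ifelse(is.na(cohort$fine_label), "", cohort$fine_label),
    treatment = fmt_bool(cohort$treatment),
    compound_het = vapply(cohort$compound_het, function(g) paste(sort(g), collapse = ";"),
                          character(1L)),
    cnv = vapply(cohort$cnv, function(g) paste(sort(g), collapse = ";"), character(1L)),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(cohort$clinical))
    for (v in names(cohort$clinical)) df[[v]] <- fmt_bool(cohort$clinical[[v]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a partition TSV (`gene TAB community_id`)
#' @param partition An `ml_partition` (or coercible).
#' @param path File path.
#' @return `read_partition` returns an `ml_partition`.
#' @export
write_partition <- function(partition, path) {
  p <- as_partition(partition)
  writeLines(c("gene\tcommunity",
               sprintf("%s\t%d", names(p), unclass(p))), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  lines <- .read_lines(path)
  if (length(lines) && identical(lines[[1L]], "gene\tcommunity"))
    lines <- lines[-1L]
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop(sprintf("malformed partition row in %s", path), call. = FALSE)
  as_partition(stats::setNames(
    as.integer(vapply(parts, `[[`, character(1L), 2L)),
    vapply(parts, `[[`, character(1L), 1L)))
}

#' Archive / restore a resolution sweep
#'
#' `write_sweep` stores one partition TSV per grid value plus a
#' `manifest.json` with the grid, per-value seeds, modularity values and
#' community counts (and a note that the even spacing of the default grid is
#' a package choice). `read_sweep` restores the `ml_sweep`.
#'
#' @param sweep An `ml_sweep`.
#' @param dir Directory (created if needed).
#' @return `read_sweep` returns an `ml_sweep`.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "ml_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sweep$grid))
    write_partition(sweep$partitions[[i]],
                    file.path(dir, sprintf("partition_%02d.tsv", i)))
  manifest <- list(grid = unclass(sweep$grid), seeds = sweep$seeds, Q = sweep$Q,
                   n_communities = sweep$n_communities,
                   n_nodes = length(sweep$nodes),
                   grid_note = "grid spacing within the resolution interval is a package choice")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  partitions <- lapply(seq_along(manifest$grid), function(i) {
    p <- read_partition(file.path(dir, sprintf("partition_%02d.tsv", i)))
    attr(p, "gamma") <- manifest$grid[[i]]
    attr(p, "seed") <- manifest$seeds[[i]]
    attr(p, "Q") <- manifest$Q[[i]]
    p
  })
  structure(list(grid = resolution_grid(values = manifest$grid),
                 partitions = partitions,
                 seeds = as.integer(manifest$seeds),
                 Q = as.numeric(manifest$Q),
                 n_communities = as.integer(manifest$n_communities),
                 nodes = names(partitions[[1L]])),
            class = "ml_sweep")
}

#' Write a module report as JSON
#'
#' @param modules An `ml_modules` list.
#' @param path Output path.
#' @param core_sizes Optional named numeric vector of persistent-core sizes.
#' @export
write_module_report <- function(modules, path, core_sizes = NULL) {
  entries <- lapply(modules, function(m) {
    list(size = length(m$genes), threshold = m$threshold,
         anchored = m$anchored, anchors = as.list(m$anchors),
         genes = as.list(m$genes))
  })
  jsonlite::write_json(list(n_modules = length(modules), modules = entries,
                            persistent_core_sizes = as.list(core_sizes)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
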