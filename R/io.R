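#' Tumor stage levels
#'
#' Ordered clinical stage labels used throughout the package. Stage I is the
#' default control (lowest-malignancy) group.
#' @export
stage_levels <- c("I", "II", "III", "IV")

# ---- expression tibble helpers ----------------------------------------------

#' Convert an expression tibble to a numeric matrix
#'
#' Expression data travel through the package as a tibble whose first column
#' (`gene_id`) identifies the gene and whose remaining columns are samples.
#' This helper extracts the numeric genes-by-samples matrix with gene ids as
#' row names.
#'
#' @param x expression tibble (`gene_id` + one numeric column per sample).
#' @return numeric matrix, rows = genes, columns = samples.
#' @export
expr_values <- function(x) {
  check_expr_tbl(x)
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

#' Build an expression tibble from a genes-by-samples matrix
#'
#' @param m numeric matrix with gene row names and sample column names.
#' @return expression tibble.
#' @export
as_expr_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

check_expr_tbl <- function(x) {
  if (!is.data.frame(x) || names(x)[1] != "gene_id") {
    abort("expected an expression tibble with first column `gene_id`")
  }
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("duplicate gene_id: ",
                 paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", ")))
  }
  smp <- setdiff(names(x), "gene_id")
  if (anyDuplicated(smp)) abort("duplicate sample ids in expression columns")
  invisible(x)
}

check_cohort <- function(cohort, x = NULL, min_per_stage = 0L) {
  if (!is.data.frame(cohort) || !all(c("sample_id", "stage") %in% names(cohort))) {
    abort("expected a cohort tibble with columns `sample_id` and `stage`")
  }
  if (anyDuplicated(cohort$sample_id)) abort("duplicate sample_id in cohort")
  if (!all(as.character(cohort$stage) %in% stage_levels)) {
    bad <- setdiff(unique(as.character(cohort$stage)), stage_levels)
    abort(paste0("unknown stage label: ", paste(bad, collapse = ", ")))
  }
  if (!is.null(x)) {
    missing <- setdiff(cohort$sample_id, setdiff(names(x), "gene_id"))
    if (length(missing)) {
      abort(paste0("cohort samples absent from expression matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  if (min_per_stage > 0L) {
    cnt <- table(factor(cohort$stage, levels = stage_levels))
    low <- names(cnt)[cnt > 0 & cnt < min_per_stage]
    if (length(low)) {
      abort(paste0("stages with fewer than ", min_per_stage, " samples: ",
                   paste(low, collapse = ", ")))
    }
  }
  invisible(cohort)
}

# ---- drop log ----------------------------------------------------------------

new_drop_log <- function() {
  tibble(item = character(), kind = character(),
         reason = character(), statistic = double())
}

append_drop_log <- function(log, item, kind, reason, statistic = NA_real_) {
  if (!length(item)) return(log)
  bind_rows(log, tibble(item = unname(item), kind = kind, reason = reason,
                        statistic = unname(statistic)))
}

set_drop_log <- function(x, log) {
  attr(x, "drop_log") <- log
  x
}

#' Retrieve the drop log of a filtered object
#'
#' Filtering steps (missing-value filter, zero-variance removal, unscorable
#' pathways) record every discarded gene, sample or pathway together with the
#' triggering statistic. The log rides along as an attribute.
#'
#' @param x an object returned by a filtering function.
#' @return tibble with columns `item`, `kind`, `reason`, `statistic`.
#' @export
drop_log <- function(x) {
  attr(x, "drop_log") %||% new_drop_log()
}

# ---- readers / writers -------------------------------------------------------

#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have a header row of sample ids and a first column of gene
#' ids. Cells matching one of `missing_tokens` become `NA`.
#'
#' @param path file path.
#' @param missing_tokens strings interpreted as missing values.
#' @return expression tibble (`gene_id` + numeric sample columns).
#' @export
read_expression_matrix <- function(path, missing_tokens = c("NA", "NaN", "")) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (!length(lines)) abort("empty expression file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(lengths(fields) != width)
  if (length(bad)) {
    abort(paste0("malformed row length at line ", bad[1], " of ", path))
  }
  samples <- fields[[1]][-1]
  if (anyDuplicated(samples)) abort("duplicate sample ids in header")
  body <- fields[-1]
  genes <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  vals <- vapply(body, function(f) {
    v <- f[-1]
    v[v %in% missing_tokens] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(length(samples)))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(genes))
  dimnames(m) <- list(genes, samples)
  as_expr_tbl(m)
}

#' Write an expression tibble as TSV
#'
#' Inverse of [read_expression_matrix()]: a written file read back yields an
#' identical object (missing cells written as `NA`). Full precision is kept.
#'
#' @param x expression tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  check_expr_tbl(x)
  m <- expr_values(x)
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    v <- format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)
    v[is.na(m[i, ])] <- "NA"
    paste(c(rownames(m)[i], v), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read sample stage labels from a two-column TSV
#'
#' Stage tokens are normalised case-insensitively; Roman numerals `I`-`IV`
#' and Arabic `1`-`4` are both accepted.
#'
#' @param path file path (columns: sample id, stage; no header required, a
#'   header line `sample_id<TAB>stage` is tolerated).
#' @return cohort tibble with columns `sample_id`, `stage` (factor I-IV).
#' @export
read_stage_labels <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) abort(paste0("expected 2 tab-separated fields at line ", bad[1]))
  ids <- vapply(fields, `[[`, "", 1L)
  raw <- vapply(fields, `[[`, "", 2L)
  if (identical(tolower(ids[1]), "sample_id")) {
    ids <- ids[-1]; raw <- raw[-1]
  }
  stage <- normalize_stage(raw)
  if (anyDuplicated(ids)) abort("duplicate sample_id in stage file")
  tibble(sample_id = ids, stage = factor(stage, levels = stage_levels))
}

normalize_stage <- function(x) {
  up <- toupper(trimws(x))
  map <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV",
           "I" = "I", "II" = "II", "III" = "III", "IV" = "IV")
  out <- unname(map[up])
  if (anyNA(out)) {
    abort(paste0("unknown stage token: ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated within a set; set names must be unique.
#'
#' @param path file path.
#' @return long tibble with columns `pathway`, `description`, `gene`; pathway
#'   order follows the file.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(pathway = character(), description = character(),
                  gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 fields"))
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) abort("duplicate gene-set names in GMT")
  out <- map2(fields, names_, function(f, nm) {
    tibble(pathway = nm, description = f[2L], gene = unique(f[-(1:2)]))
  })
  out <- bind_rows(out)
  out$pathway <- factor(out$pathway, levels = names_)
  out$pathway <- as.character(out$pathway)
  attr(out, "pathway_order") <- names_
  out
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets long tibble (`pathway`, `description`, `gene`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  split_sets <- split(gene_sets, factor(gene_sets$pathway,
                                        levels = unique(gene_sets$pathway)))
  lines <- vapply(split_sets, function(d) {
    paste(c(d$pathway[1], d$description[1] %||% "", d$gene), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Validate the three pipeline inputs together
#'
#' Checks the structural invariants the pipeline relies on: unique ids, all
#' cohort samples present in the matrix, at least two samples per represented
#' stage, non-empty gene sets.
#'
#' @param expression expression tibble.
#' @param cohort cohort tibble.
#' @param gene_sets gene-set tibble (optional).
#' @return tibble summarising counts, invisibly errors on violation.
#' @export
validate_inputs <- function(expression, cohort, gene_sets = NULL) {
  check_expr_tbl(expression)
  check_cohort(cohort, expression, min_per_stage = 2L)
  n_sets <- 0L
  if (!is.null(gene_sets)) {
    if (any(!nzchar(gene_sets$gene))) abort("empty gene id in gene sets")
    sizes <- table(gene_sets$pathway)
    if (any(sizes == 0)) abort("empty gene set")
    n_sets <- length(sizes)
  }
  tibble(
    n_genes = nrow(expression),
    n_samples = ncol(expression) - 1L,
    n_labeled = nrow(cohort),
    n_missing_cells = sum(is.na(expr_values(expression))),
    n_gene_sets = n_sets
  )
}
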