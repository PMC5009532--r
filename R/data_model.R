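# Domain containers and TSV readers/writers shared by every pipeline stage.
# Gene and sample identifiers are opaque, case-sensitive strings.

#' Construct an expression matrix
#'
#' The universal input container of the pipeline: a genes x samples numeric
#' matrix with unique row (gene) and column (sample) identifiers, an optional
#' per-sample condition or cohort label, and a flag recording whether values
#' are on a log-like scale.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; must carry
#'   unique, non-empty dimnames and contain only finite values.
#' @param condition Optional character vector of per-sample labels (e.g.
#'   `"tumor"`/`"normal"` or a cohort tag), one per column of `values`.
#' @param log_scale Logical flag: values are on a log-like scale (default TRUE).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `condition`, `log_scale`.
#' @export
expression_matrix <- function(values, condition = NULL, log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gn <- rownames(values); sn <- colnames(values)
  if (is.null(gn) || is.null(sn))
    stop("'values' must have row (gene) and column (sample) names")
  if (anyDuplicated(gn)) stop("duplicated gene identifiers")
  if (anyDuplicated(sn)) stop("duplicated sample identifiers")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != ncol(values))
      stop("'condition' must have one label per sample")
    names(condition) <- sn
  }
  structure(list(values = values, condition = condition,
                 log_scale = isTRUE(log_scale)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_scale) "log" else "linear"))
  if (!is.null(x$condition))
    print(table(condition = x$condition))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
genes <- function(m) rownames(m$values)

#' Sample identifiers of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
samples <- function(m) colnames(m$values)

#' Subset an expression matrix by samples belonging to one condition
#' @param m An `ExpressionMatrix` with condition labels.
#' @param condition Label to keep.
#' @return An `ExpressionMatrix` restricted to the matching samples.
#' @export
subset_condition <- function(m, condition) {
  if (is.null(m$condition)) stop("matrix carries no condition labels")
  keep <- m$condition == condition
  if (!any(keep)) stop(sprintf("no samples with condition '%s'", condition))
  expression_matrix(m$values[, keep, drop = FALSE],
                    condition = m$condition[keep], log_scale = m$log_scale)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers and
#' gene identifiers in the first column. Duplicate gene rows are collapsed by
#' their arithmetic mean (with a message); duplicate sample ids are an error,
#' as is any cell that does not parse as a finite number.
#'
#' @param path Path to the TSV file.
#' @param log_flag Logical: are the values log-scale? Stored on the result.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, log_flag = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample identifiers in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    message(sprintf("collapsing %d duplicated gene id(s) by mean", length(dup)))
    num <- rowsum(num, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- unique(raw[[1]])
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  expression_matrix(num, log_scale = log_flag)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces them exactly.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path) {
  chr <- formatC(m$values, digits = 17, format = "g")
  out <- cbind(gene = genes(m), chr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("gene", samples(m)))
  invisible(path)
}

#' Align an expression matrix to a fixed gene universe
#'
#' Returns a matrix with exactly the universe's genes in the universe's
#' order; genes absent from the input are filled with constant zero for all
#' samples (the convention used when a cohort lacks some signature genes).
#'
#' @param m An `ExpressionMatrix`.
#' @param universe Non-empty character vector of gene ids (ordered, unique).
#' @return An `ExpressionMatrix` over `universe`.
#' @export
align_to_gene_universe <- function(m, universe) {
  universe <- as.character(universe)
  if (length(universe) == 0) stop("gene universe must be non-empty")
  if (anyDuplicated(universe)) stop("gene universe contains duplicates")
  out <- matrix(0, nrow = length(universe), ncol = ncol(m$values),
                dimnames = list(universe, samples(m)))
  hit <- intersect(universe, genes(m))
  out[hit, ] <- m$values[hit, , drop = FALSE]
  expression_matrix(out, condition = m$condition, log_scale = m$log_scale)
}

#' Construct a candidate regulatory library
#'
#' An edge list of ordered (regulator, target) pairs. Self-loops are dropped
#' with a warning reporting how many; duplicate edges are deduplicated.
#'
#' @param edges Data frame with columns `regulator` and `target`.
#' @return Object of class `RegulatoryLibrary`: list with `edges` (data frame)
#'   and `regulators` (character vector of distinct regulator ids).
#' @export
regulatory_library <- function(edges) {
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  loops <- edges$regulator == edges$target
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(list(edges = edges, regulators = sort(unique(edges$regulator))),
            class = "RegulatoryLibrary")
}

#' @export
print.RegulatoryLibrary <- function(x, ...) {
  cat(sprintf("RegulatoryLibrary: %d edges, %d regulators, %d targets\n",
              nrow(x$edges), length(x$regulators),
              length(unique(x$edges$target))))
  invisible(x)
}

#' Targets of a regulator in a library
#' @param library A `RegulatoryLibrary`.
#' @param tf Regulator id.
#' @return Character vector of target ids (possibly empty).
#' @export
targets_of <- function(library, tf) {
  library$edges$target[library$edges$regulator == tf]
}

#' Read a TF->target edge list from a two-column TSV
#' @param path Path to the file (no header; columns regulator, target).
#' @param header Logical: first line is a header (default FALSE).
#' @return A `RegulatoryLibrary`.
#' @export
read_edges <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2) stop("edge list needs two columns: regulator, target")
  regulatory_library(data.frame(regulator = df[[1]], target = df[[2]]))
}

#' Construct a gene set
#' @param name Set name.
#' @param members Non-empty character vector of gene ids; deduplicated.
#' @return Object of class `GeneSet`: list with `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set members must be non-empty")
  structure(list(name = as.character(name), members = members),
            class = "GeneSet")
}

#' Read a gene set from a plain list or GMT file
#'
#' A file whose lines contain tabs is parsed as GMT (set name, description,
#' then member ids); otherwise one gene id per line. For a GMT file with a
#' single set (or a plain list) a single `GeneSet` is returned; a multi-set
#' GMT yields a named list of `GeneSet`s.
#'
#' @param path Path to the file.
#' @param name Name for a plain one-per-line set (default: file base name).
#' @return A `GeneSet`, or a named list of them for multi-set GMT input.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty gene set file")
  if (any(grepl("\t", lines, fixed = TRUE))) {
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stop("malformed GMT line: ", l)
      gene_set(f[1], f[-(1:2)])
    })
    names(sets) <- vapply(sets, `[[`, character(1), "name")
    if (length(sets) == 1) sets[[1]] else sets
  } else {
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
    gene_set(name, trimws(lines))
  }
}

#' Construct a clinical table
#'
#' @param df Data frame with columns `sample_id`, `survival_time` (years,
#'   non-negative), `event` (1 = death observed, 0 = censored) and optionally
#'   `age_at_diagnosis` and `grade`. Extra columns are preserved.
#' @return A validated data frame of class `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "survival_time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$survival_time <- as.numeric(df$survival_time)
  df$event <- as.numeric(df$event)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  if (any(!is.finite(df$survival_time)) || any(df$survival_time < 0))
    stop("survival_time must be finite and non-negative")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  rownames(df) <- NULL
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a clinical table from TSV
#' @param path Path to a TSV with header `sample_id`, `survival_time`, `event`
#'   (plus optional columns).
#' @return A `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path, header = TRUE, sep = "\t"))
}

#' Write a data frame (or clinical table) to TSV
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
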