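# Reading, validation, alignment and preprocessing of cohort matrices.
#
# All delimited files follow one dialect: tab-separated UTF-8, a header row of
# column identifiers, and the first column holding row identifiers.

#' Read a labelled matrix from a tab-delimited file
#'
#' Expects one header row of column identifiers and a first column of row
#' identifiers. Values are parsed as numeric; with `what = "binary"` they must
#' additionally be 0 or 1.
#'
#' @param path path to a TSV file.
#' @param what `"numeric"` (default) or `"binary"`.
#' @return a numeric matrix with row and column names in file order.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, what = c("numeric", "binary")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L) stop("matrix file needs row ids plus >=1 column: ", path,
                           call. = FALSE)
  row_ids <- raw[[1L]]
  check_unique_ids(row_ids, "row ids")
  check_unique_ids(colnames(raw)[-1L], "column ids")
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row '%s', column '%s' in %s",
                 row_ids[bad[1L]], colnames(raw)[-1L][bad[2L]], path),
         call. = FALSE)
  }
  dimnames(num) <- list(row_ids, colnames(raw)[-1L])
  if (what == "binary" && !all(num %in% c(0, 1))) {
    stop("matrix expected to be binary (0/1): ", path, call. = FALSE)
  }
  num
}

#' Write a labelled matrix to a tab-delimited file
#'
#' Inverse of [read_matrix()]: row names become the first column, column names
#' the header. Values are written with full precision so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param id_label header label for the row-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_label = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), format(x, digits = 17, trim = TRUE,
                                       scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_label, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the most variable genes
#'
#' Retains the `k` genes (rows) with the largest variance across samples,
#' preserving the original row order among the survivors. Variance ties are
#' broken by input order, so the result is deterministic.
#'
#' @param expr genes x samples numeric matrix.
#' @param k number of genes to keep (default 5000).
#' @return the restricted matrix.
#' @export
select_top_variable_genes <- function(expr, k = 5000L) {
  stopifnot(is.matrix(expr), k >= 1L, ncol(expr) >= 1L)
  n <- nrow(expr)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d available genes; keeping all", k, n))
    return(expr)
  }
  v <- apply(expr, 1L, var)
  keep <- sort(order(-v)[seq_len(k)])
  expr[keep, , drop = FALSE]
}

#' Mean-centre profiles of a matrix
#'
#' Centres each profile (row or column) by its own mean and records the
#' offsets in the `"centring_means"` attribute. When `reference_means` is
#' supplied (e.g. training-set means applied to held-out data) those offsets
#' are subtracted instead; they must be named consistently with the centred
#' margin.
#'
#' @param x numeric matrix.
#' @param margin 1 to centre rows (gene profiles), 2 to centre columns
#'   (protein features).
#' @param reference_means optional named numeric vector of stored offsets.
#' @return the centred matrix with attribute `centring_means`.
#' @export
mean_center <- function(x, margin = 1L, reference_means = NULL) {
  stopifnot(is.matrix(x), margin %in% c(1L, 2L))
  stop_if_na(x, "matrix")
  ids <- dimnames(x)[[margin]]
  if (is.null(reference_means)) {
    mu <- if (margin == 1L) rowMeans(x) else colMeans(x)
  } else {
    if (!is.null(names(reference_means)) && !is.null(ids)) {
      if (!all(ids %in% names(reference_means))) {
        stop("reference_means do not cover all profiles", call. = FALSE)
      }
      mu <- reference_means[ids]
    } else {
      if (length(reference_means) != dim(x)[margin]) {
        stop("reference_means length does not match matrix", call. = FALSE)
      }
      mu <- reference_means
    }
  }
  out <- if (margin == 1L) x - mu else sweep(x, 2L, mu, "-")
  attr(out, "centring_means") <- setNames(as.numeric(mu), ids)
  out
}

#' Centring offsets recorded by [mean_center()]
#' @param x a matrix returned by [mean_center()].
#' @return named numeric vector of offsets.
#' @export
centring_means <- function(x) attr(x, "centring_means")

#' Build the binary somatic-alteration matrix
#'
#' Mutation calls are filtered to non-silent variants in putative driver genes
#' (driver q-value below `mut_q`) that recur in at least `min_recurrence`
#' samples. Copy-number events use discrete calls in -2..2: a gene is altered
#' in a sample only at homozygous deletion (-2) or high-level amplification
#' (+2), kept when the region q-value is below `cna_q` and the event recurs in
#' at least `min_recurrence` samples. Amplifications and deletions of the same
#' gene are separate alterations. Output columns are named
#' `<gene>_mut` / `<gene>_amp` / `<gene>_del` and tagged with their kind.
#'
#' @param mutations data frame with columns `sample_id`, `gene`,
#'   `variant_class` (`"Silent"` marks silent calls) and optionally `q_value`
#'   (per-gene driver q; absent means 0, i.e. always significant).
#' @param cna_calls optional gene x sample integer matrix of discrete calls in
#'   \{-2,...,2\}.
#' @param cna_q_values optional named numeric vector of per-gene region
#'   q-values for `cna_calls`.
#' @param samples character vector giving the canonical sample order of the
#'   output.
#' @param min_recurrence minimum number of altered samples (default 10).
#' @param mut_q driver q-value cutoff (default 0.05).
#' @param cna_q region q-value cutoff (default 0.001).
#' @return samples x alterations binary matrix with attributes
#'   `alteration_kind` (mutation/amplification/deletion) and `alteration_gene`.
#' @export
build_alteration_matrix <- function(mutations = NULL, cna_calls = NULL,
                                    cna_q_values = NULL, samples,
                                    min_recurrence = 10L, mut_q = 0.05,
                                    cna_q = 0.001) {
  stopifnot(is.character(samples), length(samples) >= 1L)
  check_unique_ids(samples, "sample ids")
  cols <- list()
  kinds <- character()
  genes <- character()

  if (!is.null(mutations) && nrow(mutations) > 0L) {
    stopifnot(all(c("sample_id", "gene", "variant_class") %in%
                    colnames(mutations)))
    keep <- mutations$variant_class != "Silent"
    if (!any(keep)) {
      message("all mutation calls are silent; mutation block is empty")
    }
    mut <- mutations[keep, , drop = FALSE]
    if (!"q_value" %in% colnames(mut)) mut$q_value <- 0
    for (g in unique(mut$gene)) {
      rows <- mut[mut$gene == g, , drop = FALSE]
      if (min(rows$q_value) >= mut_q) next
      carriers <- unique(rows$sample_id)
      carriers <- carriers[carriers %in% samples]
      if (length(carriers) < min_recurrence) next
      v <- as.numeric(samples %in% carriers)
      cols[[paste0(g, "_mut")]] <- v
      kinds <- c(kinds, "mutation")
      genes <- c(genes, g)
    }
  }

  if (!is.null(cna_calls)) {
    stopifnot(is.matrix(cna_calls))
    if (!all(cna_calls %in% -2:2)) {
      stop("CNA calls must lie in {-2,-1,0,1,2}", call. = FALSE)
    }
    cn <- cna_calls[, samples, drop = FALSE]
    qv <- cna_q_values %||% setNames(rep(0, nrow(cn)), rownames(cn))
    for (g in rownames(cn)) {
      if (qv[[g]] >= cna_q) next
      for (ev in c(amp = 2, del = -2)) {
        v <- as.numeric(cn[g, ] == ev)
        if (sum(v) < min_recurrence) next
        nm <- paste0(g, "_", names(which(c(amp = 2, del = -2) == ev)))
        cols[[nm]] <- v
        kinds <- c(kinds, if (ev == 2) "amplification" else "deletion")
        genes <- c(genes, g)
      }
    }
  }

  out <- if (length(cols) == 0L) {
    matrix(numeric(0), nrow = length(samples), ncol = 0L,
           dimnames = list(samples, character(0)))
  } else {
    m <- do.call(cbind, cols)
    dimnames(m) <- list(samples, names(cols))
    m
  }
  attr(out, "alteration_kind") <- setNames(kinds, colnames(out))
  attr(out, "alteration_gene") <- setNames(genes, colnames(out))
  out
}

#' Drop transcription factors not expressed in enough samples
#'
#' A TF column of the motif-hit matrix is retained when the fraction of
#' samples in which its own gene is expressed (raw abundance strictly above
#' `expressed_threshold`) is at least `min_fraction`; the boundary is
#' inclusive. TF identifiers that cannot be resolved to a gene row of
#' `raw_expression` are reported and dropped.
#'
#' @param motifs genes x TFs binary matrix.
#' @param raw_expression genes x samples matrix of pre-centring expression.
#' @param min_fraction minimum expressed fraction (default 0.4).
#' @param expressed_threshold abundance above which a gene counts as
#'   expressed (default 0, the log-scale zero floor).
#' @return the filtered motif matrix.
#' @export
filter_tf_columns <- function(motifs, raw_expression, min_fraction = 0.4,
                              expressed_threshold = 0) {
  stopifnot(is.matrix(motifs), is.matrix(raw_expression))
  tfs <- colnames(motifs)
  resolvable <- tfs %in% rownames(raw_expression)
  if (any(!resolvable)) {
    warning("dropping TFs with no matching expression row: ",
            paste(tfs[!resolvable], collapse = ", "))
  }
  tfs <- tfs[resolvable]
  frac <- rowMeans(raw_expression[tfs, , drop = FALSE] > expressed_threshold)
  keep <- tfs[frac >= min_fraction]
  motifs[, keep, drop = FALSE]
}

#' Remove motif columns with near-duplicate target sets
#'
#' Greedy pass in column order: a TF column is dropped when the Jaccard
#' similarity of its target set with any previously retained column is at
#' least `similarity_threshold`. Removals are reported together with the
#' retained partner.
#'
#' @param motifs genes x TFs binary matrix.
#' @param similarity_threshold Jaccard cutoff in (0, 1] (default 0.8).
#' @return the de-duplicated motif matrix.
#' @export
deduplicate_motifs <- function(motifs, similarity_threshold = 0.8) {
  stopifnot(is.matrix(motifs), all(motifs %in% c(0, 1)),
            similarity_threshold > 0, similarity_threshold <= 1)
  retained <- integer(0)
  removed <- character(0)
  for (j in seq_len(ncol(motifs))) {
    dup_of <- NA_character_
    for (i in retained) {
      inter <- sum(motifs[, i] & motifs[, j])
      uni <- sum(motifs[, i] | motifs[, j])
      jac <- if (uni == 0) 1 else inter / uni  # two empty sets are duplicates
      if (jac >= similarity_threshold) {
        dup_of <- colnames(motifs)[i]
        break
      }
    }
    if (is.na(dup_of)) {
      retained <- c(retained, j)
    } else {
      removed <- c(removed, sprintf("%s (kept %s)", colnames(motifs)[j],
                                    dup_of))
    }
  }
  if (length(removed) > 0L) {
    message("removed ", length(removed), " near-duplicate motifs: ",
            paste(removed, collapse = "; "))
  }
  motifs[, retained, drop = FALSE]
}

#' Assemble an aligned cohort bundle
#'
#' Re-orders every component to the expression matrix's sample order (the
#' canonical order) and to its gene order, validates identifiers and rejects
#' missing values. All downstream stages assume this alignment.
#'
#' @param expression genes x samples numeric matrix (log-scale).
#' @param motifs genes x TFs binary matrix covering the expression genes.
#' @param proteins samples x protein-features numeric matrix.
#' @param alterations optional samples x alterations binary matrix.
#' @param clinical optional data frame with columns `sample_id`,
#'   `time_months`, `event` and optionally `covariate`, `subgroup`.
#' @return an object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(expression, motifs, proteins, alterations = NULL,
                          clinical = NULL) {
  stopifnot(is.matrix(expression), is.matrix(motifs), is.matrix(proteins))
  stop_if_na(expression, "expression")
  stop_if_na(motifs, "motifs")
  stop_if_na(proteins, "proteins")
  samples <- colnames(expression)
  genes <- rownames(expression)
  check_unique_ids(samples, "sample ids")
  check_unique_ids(genes, "gene ids")
  if (!all(genes %in% rownames(motifs))) {
    stop("motif matrix is missing genes present in the expression matrix",
         call. = FALSE)
  }
  motifs <- motifs[genes, , drop = FALSE]
  if (!all(motifs %in% c(0, 1))) stop("motif matrix must be binary",
                                      call. = FALSE)
  if (!all(samples %in% rownames(proteins))) {
    stop("protein matrix is missing samples present in the expression matrix",
         call. = FALSE)
  }
  proteins <- proteins[samples, , drop = FALSE]
  if (!is.null(alterations)) {
    stop_if_na(alterations, "alterations")
    if (!all(samples %in% rownames(alterations))) {
      stop("alteration matrix is missing samples", call. = FALSE)
    }
    kind <- attr(alterations, "alteration_kind")
    gene <- attr(alterations, "alteration_gene")
    alterations <- alterations[samples, , drop = FALSE]
    attr(alterations, "alteration_kind") <- kind
    attr(alterations, "alteration_gene") <- gene
    if (ncol(alterations) > 0L && !all(alterations %in% c(0, 1))) {
      stop("alteration matrix must be binary", call. = FALSE)
    }
  }
  if (!is.null(clinical)) {
    stopifnot(all(c("sample_id", "time_months", "event") %in%
                    colnames(clinical)))
    if (!all(samples %in% clinical$sample_id)) {
      stop("clinical table is missing samples", call. = FALSE)
    }
    clinical <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
    rownames(clinical) <- NULL
    if (any(clinical$time_months < 0) || !all(clinical$event %in% c(0, 1))) {
      stop("clinical table: time_months must be >= 0 and event in {0,1}",
           call. = FALSE)
    }
  }
  structure(list(expression = expression, motifs = motifs,
                 proteins = proteins, alterations = alterations,
                 clinical = clinical),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle\n")
  cat(sprintf("  expression: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  motifs:     %d genes x %d TFs\n",
              nrow(x$motifs), ncol(x$motifs)))
  cat(sprintf("  proteins:   %d samples x %d features\n",
              nrow(x$proteins), ncol(x$proteins)))
  if (!is.null(x$alterations)) {
    cat(sprintf("  alterations: %d binary events\n", ncol(x$alterations)))
  }
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical:   %d samples, %d events\n",
                nrow(x$clinical), sum(x$clinical$event)))
  }
  invisible(x)
}
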