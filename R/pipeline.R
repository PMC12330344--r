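#' Read a gene-by-cell count matrix
#'
#' Supports a 10x-style MTX triplet directory (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`) or a dense TSV/CSV with gene rownames and cell column
#' names. Entries must be non-negative integers.
#'
#' @param path directory (mtx) or file (tsv/csv).
#' @param format one of `"auto"`, `"mtx"`, `"tsv"`, `"csv"`.
#' @return integer matrix, genes x cells, with dimnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx" else
      if (grepl("\\.csv$", path)) "csv" else "tsv"
  }
  if (format == "mtx") {
    mm <- file.path(path, "matrix.mtx")
    if (!file.exists(mm)) stop("no matrix.mtx under ", path)
    M <- as.matrix(Matrix::readMM(mm))
    feats <- read.table(file.path(path, "features.tsv"), sep = "\t",
                        header = FALSE, stringsAsFactors = FALSE)
    bcs <- read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                      header = FALSE, stringsAsFactors = FALSE)
    rownames(M) <- feats[[1]]
    colnames(M) <- bcs[[1]]
  } else {
    M <- as.matrix(read.table(path, sep = if (format == "csv") "," else "\t",
                              header = TRUE, row.names = 1,
                              check.names = FALSE))
  }
  if (any(M != floor(M)) || any(M < 0))
    stop("count matrix must contain non-negative integers")
  storage.mode(M) <- "integer"
  M
}

#' Write a gene-by-cell count matrix
#'
#' @param counts integer matrix, genes x cells, with dimnames.
#' @param path output file (tsv/csv) or directory (mtx).
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    write.table(data.frame(rownames(counts)),
                file.path(path, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(data.frame(colnames(counts)),
                file.path(path, "barcodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    write.table(counts, path, sep = if (format == "csv") "," else "\t",
                quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Gene filters for co-expression screening
#'
#' Droplet mode removes genes on a user-supplied exclusion list (e.g.
#' mitochondrial, housekeeping, non-protein-coding), genes with more than
#' 70% zero counts, and genes whose empirical 97.5% upper quantile
#' (nearest-rank rule) is below 4. Plate mode additionally requires a
#' two-level group label and removes genes whose normalized expression has a
#' standard deviation below 0.4 in either group, or whose group standard
#' deviations differ by less than 0.1 in absolute value. If no normalized
#' matrix is supplied, the built-in fallback `log1p(counts * median(S)/S)`
#' with per-cell depth `S` is used.
#'
#' @param counts integer matrix, genes x cells.
#' @param exclude character vector of gene names to drop a priori.
#' @param mode `"droplet"` or `"plate"`.
#' @param groups per-cell group labels (plate mode, two levels).
#' @param normalized optional normalized matrix, same shape as `counts`.
#' @param zero_prop,quantile_min,sd_min,sd_diff_min filter thresholds.
#' @return character vector of retained gene names.
#' @export
filter_genes <- function(counts, exclude = character(),
                         mode = c("droplet", "plate"), groups = NULL,
                         normalized = NULL, zero_prop = 0.70,
                         quantile_min = 4, sd_min = 0.4, sd_diff_min = 0.1) {
  mode <- match.arg(mode)
  genes <- rownames(counts)
  if (is.null(genes)) stop("counts must have gene rownames")
  keep <- !(genes %in% exclude)
  zf <- rowMeans(counts == 0)
  keep <- keep & (zf <= zero_prop)
  q <- apply(counts, 1, quantile, probs = 0.975, type = 1, names = FALSE)
  keep <- keep & (q >= quantile_min)
  if (mode == "plate") {
    if (is.null(groups)) stop("plate mode requires per-cell group labels")
    groups <- as.character(groups)
    lev <- sort(unique(groups))
    if (length(lev) != 2) stop("plate mode requires exactly two groups")
    if (is.null(normalized)) {
      S <- colSums(counts)
      normalized <- log1p(t(t(counts) * (stats::median(S) / S)))
    }
    sd1 <- apply(normalized[, groups == lev[1], drop = FALSE], 1, sd)
    sd2 <- apply(normalized[, groups == lev[2], drop = FALSE], 1, sd)
    keep <- keep & (sd1 >= sd_min) & (sd2 >= sd_min) &
      (abs(sd1 - sd2) >= sd_diff_min)
  }
  genes[keep]
}

#' Enumerate unordered gene pairs
#'
#' All `n(n-1)/2` unordered pairs in deterministic lexicographic order.
#'
#' @param genes character vector of at least two gene names.
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
enumerate_pairs <- function(genes) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2) stop("need at least two genes")
  genes <- sort(genes)
  idx <- combn(length(genes), 2)
  data.frame(gene1 = genes[idx[1, ]], gene2 = genes[idx[2, ]],
             stringsAsFactors = FALSE)
}

.check_metadata <- function(counts, metadata) {
  if (is.null(metadata$cell_id)) stop("metadata must contain 'cell_id'")
  miss <- setdiff(colnames(counts), metadata$cell_id)
  if (length(miss))
    stop("metadata missing cell barcode(s): ", paste(head(miss, 5), collapse = ", "))
  metadata[match(colnames(counts), metadata$cell_id), , drop = FALSE]
}

.pair_row_failed <- function(g1, g2, msg) {
  data.frame(gene1 = g1, gene2 = g2, rho_g0 = NA_real_, rho_g1 = NA_real_,
             abs_delta_rho = NA_real_, tau1 = NA_real_, se = NA_real_,
             p = NA_real_, p_bh = NA_real_, converged = FALSE,
             note = msg, stringsAsFactors = FALSE)
}

#' Screen all gene pairs for differential co-expression
#'
#' Fits the zero-inflated copula mixed model to every unordered pair of the
#' supplied genes, Wald-tests the condition effect on the correlation
#' predictor, and BH-adjusts the p-values of the converged fits. Per-pair
#' failures are recorded with a flag and never abort the screen. With a
#' `cache_dir`, per-pair results are stored on disk so an interrupted screen
#' resumes where it stopped and a rerun reproduces the table exactly.
#'
#' @param counts integer matrix, genes x cells (already filtered).
#' @param metadata data.frame with `cell_id`, `patient`, the condition
#'   column, and optionally `depth` (defaults to the column sums of
#'   `counts`; supply depths computed before gene filtering when available).
#' @param spec a [model_spec]; its condition must be a metadata column.
#' @param control a [fit_control].
#' @param genes optional subset of genes to screen.
#' @param cache_dir optional directory for per-pair result caching.
#' @param verbose print per-pair progress.
#' @return data.frame of class `coexmix_screen` with one row per pair:
#'   group-wise correlations, `abs_delta_rho`, `tau1`, `se`, `p`, `p_bh`,
#'   `converged`.
#' @export
screen_pairs <- function(counts, metadata, spec = pair_spec(),
                         control = fit_control(), genes = NULL,
                         cache_dir = NULL, verbose = FALSE) {
  metadata <- .check_metadata(counts, metadata)
  if (is.null(metadata$depth)) metadata$depth <- colSums(counts)
  if (is.null(genes)) genes <- rownames(counts)
  pairs <- enumerate_pairs(genes)
  if (!is.null(cache_dir))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(g1, "__", g2, ".rds")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[i]] <- readRDS(cache_file)
      next
    }
    row <- tryCatch({
      gp <- gene_pair_data(counts[g1, ], counts[g2, ], metadata,
                           genes = c(g1, g2))
      fit <- fit_pair(gp, spec, control)
      w <- wald(fit)
      nr <- natural_scale_rho(fit)
      data.frame(gene1 = g1, gene2 = g2,
                 rho_g0 = nr$rho_group0, rho_g1 = nr$rho_group1,
                 abs_delta_rho = nr$delta,
                 tau1 = w$estimate, se = w$se,
                 p = if (w$flagged) NA_real_ else w$p,
                 p_bh = NA_real_,
                 converged = isTRUE(fit$converged) && !w$singular,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e) .pair_row_failed(g1, g2, conditionMessage(e)))
    if (!is.null(cache_file)) saveRDS(row, cache_file)
    rows[[i]] <- row
    if (verbose) message(sprintf("[%d/%d] %s-%s", i, nrow(pairs), g1, g2))
  }
  tab <- do.call(rbind, rows)
  tab$p_bh <- bh_adjust(ifelse(tab$converged, tab$p, NA_real_))
  class(tab) <- c("coexmix_screen", "data.frame")
  tab
}

#' Top differentially co-expressed pairs
#'
#' Significant pairs (BH-adjusted p below `alpha`, converged fits only)
#' ranked by the absolute change in copula correlation.
#'
#' @param tab a [screen_pairs] table.
#' @param k number of pairs to keep.
#' @param alpha BH significance cutoff; `NULL` to rank all converged pairs.
#' @return the top rows of `tab`, sorted by `abs_delta_rho` descending.
#' @export
top_table <- function(tab, k = 25, alpha = 0.05) {
  keep <- tab$converged & !is.na(tab$p_bh)
  if (!is.null(alpha)) keep <- keep & tab$p_bh < alpha
  out <- tab[keep, , drop = FALSE]
  out <- out[order(-out$abs_delta_rho), , drop = FALSE]
  head(out, k)
}
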