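#' Bundle paired gene counts with per-cell metadata
#'
#' @param y1,y2 non-negative integer count vectors for the two genes.
#' @param metadata data.frame with one row per cell; must contain a
#'   `patient` column and a positive `depth` column (total sequencing depth
#'   of the cell, computed over all genes before any filtering), plus any
#'   covariates referenced by the model specification. An optional `cell_id`
#'   column is used in error messages.
#' @param genes length-2 character vector of gene names.
#' @return object of class `gene_pair_data`.
#' @export
gene_pair_data <- function(y1, y2, metadata, genes = c("gene1", "gene2")) {
  n <- length(y1)
  if (length(y2) != n || nrow(metadata) != n)
    stop("y1, y2 and metadata must cover the same cells")
  if (any(y1 < 0) || any(y2 < 0) || any(y1 != floor(y1)) || any(y2 != floor(y2)))
    stop("counts must be non-negative integers")
  if (is.null(metadata$patient)) stop("metadata must contain a 'patient' column")
  if (is.null(metadata$depth)) stop("metadata must contain a 'depth' column")
  ids <- if (!is.null(metadata$cell_id)) as.character(metadata$cell_id) else
    as.character(seq_len(n))
  bad <- which(!complete.cases(metadata) | !is.finite(metadata$depth) |
                 metadata$depth <= 0)
  if (length(bad))
    stop("invalid or missing metadata for cell(s): ",
         paste(head(ids[bad], 5), collapse = ", "))
  meta <- as.data.frame(metadata, stringsAsFactors = FALSE)
  # character covariates become factors with metadata-sorted level order, so
  # the reference level of a two-level condition is the first sorted level
  for (cn in names(meta)) {
    if (is.character(meta[[cn]]) && cn != "cell_id")
      meta[[cn]] <- factor(meta[[cn]], levels = sort(unique(meta[[cn]])))
  }
  structure(list(y1 = as.integer(y1), y2 = as.integer(y2), meta = meta,
                 genes = genes, cell_id = ids),
            class = "gene_pair_data")
}

#' @exportS3Method base::print
print.gene_pair_data <- function(x, ...) {
  cat("gene pair data:", paste(x$genes, collapse = " / "), "\n")
  cat(" ", length(x$y1), "cells,", length(unique(x$meta$patient)), "patients\n")
  invisible(x)
}

.parse_theta_formula <- function(f, theta) {
  if (inherits(f, "formula")) f <- f else f <- as.formula(f)
  labs <- attr(terms(f), "term.labels")
  bar <- grepl("|", labs, fixed = TRUE)
  if (sum(bar) > 1)
    stop("at most one random-effect term per parameter (", theta, ")")
  rand <- NULL
  if (any(bar)) {
    parts <- strsplit(labs[bar], "\\|")[[1]]
    if (length(parts) != 2) stop("malformed random-effect term in ", theta)
    rand <- list(expr = trimws(parts[1]), group = trimws(parts[2]))
  }
  fixed_labs <- labs[!bar]
  fixed <- if (length(fixed_labs))
    as.formula(paste("~", paste(fixed_labs, collapse = " + "))) else ~1
  list(fixed = fixed, rand = rand)
}

#' Per-parameter model specification
#'
#' One formula per natural parameter. The fixed part uses ordinary formula
#' syntax; at most one random-intercept term is allowed per parameter, in one
#' of three forms:
#' \itemize{
#'   \item `(1 | patient)`: patient-level intercepts, one shared variance
#'     component.
#'   \item `(1 | patient:group)`: patient-by-group intercepts, one shared
#'     variance component.
#'   \item `(group | patient)`: patient-by-group intercepts with a separate
#'     variance component for every level of `group` (cell-means coding, not
#'     a random slope).
#' }
#' Depth offsets are placed on the two mean predictors only.
#'
#' @param mu1,mu2,sigma1,sigma2,rho,p1,p2 formulas (or strings) for the
#'   linear predictors of the seven parameters.
#' @param condition name of the binary condition covariate whose `rho`
#'   coefficient is the differential co-expression contrast.
#' @param offset logical; add `log(depth)` to the mean predictors.
#' @return object of class `coexmix_spec`.
#' @export
model_spec <- function(mu1 = ~1, mu2 = ~1, sigma1 = ~1, sigma2 = ~1,
                       rho = ~1, p1 = ~1, p2 = ~1,
                       condition = NULL, offset = TRUE) {
  fl <- list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
             rho = rho, p1 = p1, p2 = p2)
  parsed <- lapply(names(fl), function(t) .parse_theta_formula(fl[[t]], t))
  names(parsed) <- names(fl)
  structure(list(terms = parsed, condition = condition, offset = isTRUE(offset)),
            class = "coexmix_spec")
}

#' Canonical two-condition gene-pair specification
#'
#' Condition effects on all seven parameters; patient-level random intercepts
#' on the dropout predictors; patient-by-condition random intercepts on the
#' two means and the copula correlation; no random effects on the
#' over-dispersions. With `split_components = TRUE` the mean/correlation
#' intercepts get a separate variance component per condition level (the
#' longitudinal design); the default shares one component per parameter.
#'
#' @param condition name of the binary condition column.
#' @param patient name of the patient column.
#' @param random include random effects at all.
#' @param split_components separate variance components per condition level.
#' @return `coexmix_spec`.
#' @export
pair_spec <- function(condition = "group", patient = "patient",
                      random = TRUE, split_components = FALSE) {
  fx <- paste("~", condition)
  re_mu <- if (!random) "" else if (split_components)
    paste0(" + (", condition, " | ", patient, ")") else
      paste0(" + (1 | ", patient, ":", condition, ")")
  re_p <- if (!random) "" else paste0(" + (1 | ", patient, ")")
  model_spec(
    mu1 = as.formula(paste0(fx, re_mu)),
    mu2 = as.formula(paste0(fx, re_mu)),
    sigma1 = as.formula(fx),
    sigma2 = as.formula(fx),
    rho = as.formula(paste0(fx, re_mu)),
    p1 = as.formula(paste0(fx, re_p)),
    p2 = as.formula(paste0(fx, re_p)),
    condition = condition
  )
}

.rand_design <- function(rand, meta, theta) {
  if (is.null(rand)) {
    return(list(Z = matrix(0, nrow(meta), 0), comp = integer(0),
                names = character(0), comp_names = character(0)))
  }
  gvars <- trimws(strsplit(rand$group, ":", fixed = TRUE)[[1]])
  for (g in gvars) {
    if (is.null(meta[[g]]))
      stop("grouping factor '", g, "' not found in metadata")
  }
  gid <- do.call(paste, c(lapply(gvars, function(g) as.character(meta[[g]])),
                          sep = ":"))
  glev <- unique(gid) # first-appearance order
  if (identical(rand$expr, "1")) {
    Z <- outer(gid, glev, "==") * 1
    comp <- rep(1L, length(glev))
    cn <- paste0(theta, ":u:", glev)
    comp_names <- paste0(theta, ":", rand$group)
  } else {
    v <- meta[[rand$expr]]
    if (is.null(v)) stop("random-effect variable '", rand$expr, "' not found")
    v <- as.character(v)
    vlev <- sort(unique(v))
    cols <- list(); comp <- integer(0); cn <- character(0)
    for (li in seq_along(vlev)) {
      for (g in glev) {
        cols[[length(cols) + 1]] <- (gid == g & v == vlev[li]) * 1
        comp <- c(comp, li)
        cn <- c(cn, paste0(theta, ":u:", g, ":", vlev[li]))
      }
    }
    Z <- do.call(cbind, cols)
    comp_names <- paste0(theta, ":", rand$expr, "=", vlev)
  }
  list(Z = Z, comp = comp, names = cn, comp_names = comp_names)
}

#' Build design blocks for a gene pair model
#'
#' Constructs per-parameter fixed and random design matrices, the depth
#' offsets on the mean predictors, and the variance-component map that
#' aligns one smoothing parameter with every group of random coefficients.
#' Column ordering is deterministic: intercept first, fixed covariates in
#' specification order, random levels in first-appearance order.
#'
#' @param data a [gene_pair_data] object.
#' @param spec a [model_spec].
#' @return object of class `coexmix_blocks`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "gene_pair_data"), inherits(spec, "coexmix_spec"))
  meta <- data$meta
  n <- nrow(meta)
  theta <- list()
  for (t in .THETA) {
    tm <- spec$terms[[t]]
    X <- model.matrix(tm$fixed, meta)
    if (nrow(X) != n)
      stop("covariates contain missing values for parameter ", t)
    rd <- .rand_design(tm$rand, meta, t)
    off <- if (spec$offset && t %in% c("mu1", "mu2")) log(meta$depth) else
      rep(0, n)
    theta[[t]] <- list(
      X = X, Z = rd$Z, off = off,
      fixed_names = paste0(t, ":", colnames(X)),
      rand_names = rd$names,
      comp = rd$comp, comp_names = rd$comp_names
    )
  }
  # global packing: all fixed coefficients (theta order), then all random
  delta_names <- unlist(lapply(theta, function(b) b$fixed_names), use.names = FALSE)
  u_names <- unlist(lapply(theta, function(b) b$rand_names), use.names = FALSE)
  comp_names <- unlist(lapply(theta, function(b) b$comp_names), use.names = FALSE)
  n_fixed <- length(delta_names)
  pos_f <- 0L; pos_u <- n_fixed; pos_c <- 0L
  comp_id <- integer(n_fixed + length(u_names))
  for (t in .THETA) {
    b <- theta[[t]]
    kf <- ncol(b$X); kr <- ncol(b$Z)
    b$idx <- c(if (kf) pos_f + seq_len(kf) else integer(0),
               if (kr) pos_u + seq_len(kr) else integer(0))
    b$M <- cbind(b$X, b$Z)
    if (kr) comp_id[pos_u + seq_len(kr)] <- pos_c + b$comp
    pos_f <- pos_f + kf; pos_u <- pos_u + kr
    pos_c <- pos_c + length(b$comp_names)
    theta[[t]] <- b
  }
  cond_rows <- NULL
  condition_levels <- NULL
  if (!is.null(spec$condition) && !is.null(meta[[spec$condition]])) {
    cv <- meta[[spec$condition]]
    condition_levels <- if (is.factor(cv)) levels(cv) else sort(unique(cv))
    cond_rows <- match(condition_levels, as.character(cv))
  }
  structure(list(
    n = n, theta = theta,
    coef_names = c(delta_names, u_names),
    n_coef = n_fixed + length(u_names), n_fixed = n_fixed,
    comp_id = comp_id, comp_names = comp_names,
    condition = spec$condition,
    condition_levels = condition_levels, cond_rows = cond_rows
  ), class = "coexmix_blocks")
}

#' @exportS3Method base::print
print.coexmix_blocks <- function(x, ...) {
  cat("coexmix design:", x$n, "cells,", x$n_fixed, "fixed coefficients,",
      x$n_coef - x$n_fixed, "random coefficients,",
      length(x$comp_names), "variance components\n")
  invisible(x)
}

.pack_state <- function(blocks, state) {
  x <- numeric(blocks$n_coef)
  names(x) <- blocks$coef_names
  if (!is.null(state$delta)) x[seq_len(blocks$n_fixed)] <- state$delta
  if (blocks$n_coef > blocks$n_fixed && !is.null(state$u))
    x[(blocks$n_fixed + 1):blocks$n_coef] <- state$u
  x
}

.unpack_state <- function(blocks, x, lambda = NULL) {
  list(delta = setNames(x[seq_len(blocks$n_fixed)],
                        blocks$coef_names[seq_len(blocks$n_fixed)]),
       u = if (blocks$n_coef > blocks$n_fixed)
         setNames(x[(blocks$n_fixed + 1):blocks$n_coef],
                  blocks$coef_names[(blocks$n_fixed + 1):blocks$n_coef])
       else numeric(0),
       lambda = lambda)
}

# n x 7 matrix of linear predictors (mean columns include the offset)
.eta_matrix <- function(blocks, x) {
  eta <- matrix(0, blocks$n, 7)
  for (j in seq_along(.THETA)) {
    b <- blocks$theta[[.THETA[j]]]
    eta[, j] <- if (length(b$idx)) as.vector(b$M %*% x[b$idx]) + b$off else b$off
  }
  eta
}

# expanded penalty vector (0 on fixed coefficients, lambda on random ones)
.penalty_vector <- function(blocks, lambda) {
  pen <- numeric(blocks$n_coef)
  if (length(blocks$comp_names)) {
    if (is.null(names(lambda))) names(lambda) <- blocks$comp_names
    lam <- lambda[blocks$comp_names]
    if (any(is.na(lam))) stop("lambda must be named by variance component")
    pos <- blocks$comp_id > 0
    pen[pos] <- lam[blocks$comp_id[pos]]
  }
  pen
}

.inv_links <- function(eta) {
  data.frame(
    mu1 = exp(pmin(pmax(eta[, 1], -.CLIP$mu), .CLIP$mu)),
    mu2 = exp(pmin(pmax(eta[, 2], -.CLIP$mu), .CLIP$mu)),
    sigma1 = exp(pmin(pmax(eta[, 3], -.CLIP$sigma), .CLIP$sigma)),
    sigma2 = exp(pmin(pmax(eta[, 4], -.CLIP$sigma), .CLIP$sigma)),
    rho = tanh(pmin(pmax(eta[, 5], -.CLIP$rho), .CLIP$rho)),
    p1 = plogis(pmin(pmax(eta[, 6], -.CLIP$p), .CLIP$p)),
    p2 = plogis(pmin(pmax(eta[, 7], -.CLIP$p), .CLIP$p))
  )
}

#' Map coefficients to per-cell natural parameters
#'
#' Applies the inverse links (`exp` for means and over-dispersions, `tanh`
#' for the correlation, logistic for the dropout probabilities) to the
#' linear predictors, with the package's overflow clips, so the output
#' always satisfies the natural-parameter constraints.
#'
#' @param blocks a [build_design] result.
#' @param state list with elements `delta` and `u` (coefficient vectors in
#'   packing order).
#' @param cells optional integer subset of cells.
#' @return data.frame with columns `mu1, mu2, sigma1, sigma2, rho, p1, p2`.
#' @export
predict_params <- function(blocks, state, cells = NULL) {
  x <- .pack_state(blocks, state)
  eta <- .eta_matrix(blocks, x)
  out <- .inv_links(eta)
  if (!is.null(cells)) out <- out[cells, , drop = FALSE]
  out
}
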