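#' Principal component analysis of a genotype matrix
#'
#' Eigendecomposition of the sample covariance of centred (and optionally
#' scaled) dosages. Missing dosages are mean-imputed per site for the
#' decomposition only; monomorphic sites are dropped. Axis signs follow a
#' deterministic convention: the sample coordinate of largest magnitude on
#' each axis is made positive.
#'
#' @param gm a [genotype_matrix()].
#' @param n_axes number of axes to return.
#' @param scaling `"patterson"` (divide by `sqrt(p(1-p))`), `"unit"`
#'   (per-site unit variance) or `"none"`.
#' @return An object of class `gm_pca`: `coords` (samples x axes),
#'   `explained_var`, `sdev`, `n_sites`.
#' @export
gm_pca <- function(gm, n_axes = 10, scaling = c("patterson", "unit", "none")) {
  scaling <- match.arg(scaling)
  d <- gm$dosage
  if (nrow(d) < 2) stop("PCA needs at least 2 samples")
  mu <- colMeans(d, na.rm = TRUE)
  x <- sweep(d, 2, mu)
  x[is.na(x)] <- 0                      # mean imputation after centring
  p <- mu / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2) stop("PCA needs at least 2 polymorphic sites")
  x <- x[, keep, drop = FALSE]
  if (scaling == "patterson") {
    x <- sweep(x, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  } else if (scaling == "unit") {
    s <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, pmax(s, 1e-12), "/")
  }
  sv <- svd(x, nu = min(n_axes, nrow(x) - 1), nv = 0)
  k <- min(n_axes, length(sv$d), nrow(x) - 1)
  coords <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = nrow(x))
  # deterministic sign: largest-|coordinate| sample positive on each axis
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  ev <- sv$d^2
  structure(list(coords = coords, explained_var = (ev / sum(ev))[seq_len(k)],
                 sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1)),
                 n_sites = sum(keep)),
            class = "gm_pca")
}

#' @export
print.gm_pca <- function(x, ...) {
  cat("PCA:", nrow(x$coords), "samples,", x$n_sites, "sites;",
      "explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_var, 4)),
            collapse = " "), "\n")
  invisible(x)
}

# internal: one EM run of the binomial admixture model. The expected-count
# sums over sites/samples are matrix products, so no per-ancestry n x L
# intermediate is ever formed:
#   rowSums(A_k) = Q[,k] * (R1 %*% P[k,]),  colSums(A_k) = P[k,] * (R1' Q)[,k]
.admix_em_run <- function(G, M, K, Q, P, max_iter, tol, eps = 1e-6) {
  Gz <- ifelse(M, G, 0)                # missing as 0 copies observed
  G2z <- ifelse(M, 2 - G, 0)
  nn <- 2 * rowSums(M)                 # observed allele count per sample
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    Fm <- pmin(pmax(Q %*% P, eps), 1 - eps)
    ll <- sum(Gz * log(Fm) + G2z * log(1 - Fm))
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_prev) < tol || it >= max_iter) {
      converged <- abs(ll - ll_prev) < tol
      break
    }
    ll_prev <- ll
    it <- it + 1L
    R1 <- Gz / Fm                      # alt-copy responsibility scale
    R0 <- G2z / (1 - Fm)
    Qn <- Q * (R1 %*% t(P) + R0 %*% t(1 - P)) / nn
    T1 <- t(crossprod(R1, Q)) * P      # K x L expected alt copies
    T0 <- t(crossprod(R0, Q)) * (1 - P)
    Q <- Qn / rowSums(Qn)
    P <- pmin(pmax(T1 / pmax(T1 + T0, eps), eps), 1 - eps)
  }
  list(Q = Q, P = P, loglik = ll_trace[length(ll_trace)], trace = ll_trace,
       converged = converged, iterations = it)
}

#' Admixture proportions by EM under the binomial likelihood
#'
#' Maximizes the standard unsupervised admixture likelihood
#' `prod_il Binom(g_il | 2, sum_k q_ik p_kl)` by EM updates. Multiple seeded
#' restarts are screened with a short burn-in; the best is run to
#' convergence. The log-likelihood is non-decreasing across iterations (an
#' EM guarantee, recorded in `$trace`).
#'
#' @param gm a [genotype_matrix()].
#' @param K number of ancestral populations.
#' @param seed integer seed for the restarts.
#' @param max_iter iteration cap for the final run.
#' @param tol absolute log-likelihood change declaring convergence.
#' @param n_restarts random restarts screened.
#' @param burn_iter burn-in iterations per screened restart.
#' @return Object of class `admixture_fit`: `Q` (n x K, rows sum to 1), `P`
#'   (K x sites), `loglik`, `trace`, `converged`, `iterations`.
#' @export
admixture_em <- function(gm, K = 3, seed = 1L, max_iter = 400, tol = 1e-4,
                         n_restarts = 10, burn_iter = 25) {
  stopifnot(K >= 2)
  G <- gm$dosage
  M <- !is.na(G)
  if (any(rowSums(M) == 0)) stop("sample with no non-missing genotypes")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    a <- matrix(stats::rgamma(nrow(G) * K, 1), nrow(G), K)
    Q0 <- a / rowSums(a)
    p0 <- colSums(ifelse(M, G, 0)) / pmax(2 * colSums(M), 1)
    P0 <- pmin(pmax(matrix(rep(p0, each = K), K) +
                      matrix(stats::rnorm(K * ncol(G), 0, 0.1), K), 0.01),
               0.99)
    run <- .admix_em_run(G, M, K, Q0, P0, max_iter = burn_iter, tol = 0)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  fit <- .admix_em_run(G, M, K, best$Q, best$P, max_iter = max_iter,
                       tol = tol)
  if (!fit$converged) {
    warning("admixture EM did not converge in ", max_iter,
            " iterations; best state returned")
  }
  rownames(fit$Q) <- gm$samples
  colnames(fit$Q) <- paste0("K", seq_len(K))
  fit$K <- K
  class(fit) <- "admixture_fit"
  fit
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ",", nrow(x$Q), "samples, loglik =",
      format(x$loglik), if (x$converged) "(converged)" else "(not converged)",
      "\n")
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  cat("Mean ancestry proportions:\n")
  print(round(colMeans(object$Q), 3))
  cat("EM iterations:", object$iterations, "\n")
  invisible(object)
}

#' Align ancestry components to reference group labels
#'
#' Greedy matching: components are assigned, in decreasing order of mean
#' membership, to the reference group (e.g. the known pure C/S/M samples)
#' in which their mean Q is highest.
#'
#' @param Q n x K ancestry matrix.
#' @param groups named list mapping a label to the sample ids of its
#'   reference members.
#' @return `Q` with columns reordered and renamed to the labels.
#' @export
align_q <- function(Q, groups) {
  K <- ncol(Q)
  stopifnot(length(groups) == K)
  means <- sapply(groups, function(s) colMeans(Q[s, , drop = FALSE]))
  # means: K components x K groups
  assign <- rep(NA_integer_, K)
  m <- means
  for (step in seq_len(K)) {
    i <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
    assign[i["col"]] <- i["row"]
    m[i["row"], ] <- NA; m[, i["col"]] <- NA
  }
  out <- Q[, assign, drop = FALSE]
  colnames(out) <- names(groups)
  out
}

#' Ternary ancestry classification
#'
#' A sample is a parental class (C, S or M) when that ancestry exceeds 0.80
#' of its genome; otherwise a two-way class (CS, SM or MC, named by the two
#' largest components) when the smallest component is at most 0.10;
#' otherwise the balanced three-way class MCS. Ties between the two largest
#' components are broken by the fixed priority C > S > M.
#'
#' @param q numeric vector `(q_C, q_S, q_M)` or an n x 3 matrix with columns
#'   in that order (column names `C`,`S`,`M` or `q_C`,`q_S`,`q_M` accepted).
#' @param major threshold for a parental call (strictly greater than).
#' @param minor maximum third-ancestry contribution of a two-way class
#'   (less than or equal).
#' @return Character vector of classes among
#'   `C, S, M, CS, SM, MC, MCS`.
#' @export
classify_ternary <- function(q, major = 0.80, minor = 0.10) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  q <- as.matrix(q)
  stopifnot(ncol(q) == 3, all(abs(rowSums(q) - 1) < 1e-6))
  anc <- c("C", "S", "M")
  pair_name <- c(CS = "CS", SC = "CS", SM = "SM", MS = "SM",
                 MC = "MC", CM = "MC")
  apply(q, 1, function(x) {
    if (max(x) > major) return(anc[which.max(x)])
    if (min(x) <= minor) {
      big <- order(-x, seq_along(x))[1:2]   # priority C > S > M on ties
      return(unname(pair_name[paste0(anc[sort(big)], collapse = "")]))
    }
    "MCS"
  })
}

#' Ancestry profiles from a fitted Q matrix
#'
#' @param Q aligned ancestry matrix with columns `C`, `S`, `M` (see
#'   [align_q()]).
#' @inheritParams classify_ternary
#' @return data.frame `sample_id, q_C, q_S, q_M, class`.
#' @export
ancestry_profiles <- function(Q, major = 0.80, minor = 0.10) {
  stopifnot(all(c("C", "S", "M") %in% colnames(Q)))
  Q <- Q[, c("C", "S", "M")]
  data.frame(sample_id = rownames(Q), q_C = Q[, "C"], q_S = Q[, "S"],
             q_M = Q[, "M"], class = classify_ternary(Q, major, minor),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Class composition per sampling location
#'
#' Contingency table of ancestry classes by location.
#'
#' @param profiles data.frame with `sample_id` and `class` (see
#'   [ancestry_profiles()]).
#' @param sample_sheet data.frame with `sample_id` and `location`.
#' @return A table: locations in rows, the seven classes in columns.
#' @export
class_composition_report <- function(profiles, sample_sheet) {
  loc <- sample_sheet$location[match(profiles$sample_id,
                                     sample_sheet$sample_id)]
  if (anyNA(loc)) stop("profiles contain samples absent from the sheet")
  cls <- factor(profiles$class,
                levels = c("C", "S", "M", "CS", "SM", "MC", "MCS"))
  table(location = loc, class = cls)
}
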