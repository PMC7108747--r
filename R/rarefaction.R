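RAREFACTION_COMPONENTS <- c("pangenome", "persistent", "shell", "cloud",
                            "soft_core", "soft_accessory", "exact_core",
                            "exact_accessory")

#' Allowed absences under a soft-core threshold
#'
#' The number of genomes a family may be absent from while still counting
#' as soft core: floor((1 - threshold) * n). Its increments are spaced
#' ceiling(1/(1-threshold)) genomes apart, producing the stair-step of
#' soft-core rarefaction curves (every 20 genomes at the default 95%).
#'
#' @param n number of genomes sampled.
#' @param threshold soft-core presence threshold (default 0.95).
#' @return integer vector of allowed absence counts.
#' @export
allowedAbsences <- function(n, threshold = 0.95) {
  as.integer(floor((1 - threshold) * n + 1e-9))
}

#' Pangenome component sizes on a genome subset
#'
#' Families absent from every genome of the subset are excluded from all
#' counts. Exact core families are present in all n genomes; soft core in
#' at least ceiling(threshold * n); persistent/shell/cloud come from the
#' supplied partitioning of the subset.
#'
#' @param XSub a \linkS4class{PAMatrix} restricted to the subset (zero rows
#'   already dropped by the subset operator).
#' @param partitioning optional \linkS4class{Partitioning} of the subset's
#'   families; without it the partition components are NA.
#' @param softThreshold soft-core presence fraction (default 0.95).
#' @return named numeric vector over the eight components.
#' @export
componentCounts <- function(XSub, partitioning = NULL,
                            softThreshold = 0.95) {
  n <- ncol(XSub)
  if (n < 1) stop("subset must contain at least one genome")
  occ <- Matrix::rowSums(XSub@presence)
  counts <- c(
    pangenome = length(occ),
    persistent = NA_real_, shell = NA_real_, cloud = NA_real_,
    soft_core = sum(occ >= ceiling(softThreshold * n)),
    soft_accessory = NA_real_,
    exact_core = sum(occ == n),
    exact_accessory = NA_real_
  )
  counts["soft_accessory"] <- counts["pangenome"] - counts["soft_core"]
  counts["exact_accessory"] <- counts["pangenome"] - counts["exact_core"]
  if (!is.null(partitioning)) {
    lab <- partitionLabels(partitioning)[familyNames(XSub)]
    counts["persistent"] <- sum(lab == "persistent", na.rm = TRUE)
    counts["shell"] <- sum(lab == "shell", na.rm = TRUE)
    counts["cloud"] <- sum(lab == "cloud", na.rm = TRUE)
  }
  counts
}

#' Rarefaction curves of pangenome components
#'
#' For each subset size n = 1..min(maxN, N), draws \code{reps} random
#' genome subsets without replacement and records the component sizes;
#' quartiles per size, Heaps'-law fits over all replicate points with
#' n > 15, and interquartile ribbon areas summarize the curves. By default
#' every subset is re-partitioned with K re-selected between 3 and
#' \code{KFull}; set \code{partitionMode} to "fixed" to keep K = KFull, or
#' "none" to skip partition components (matrix-only curves).
#'
#' @param X a \linkS4class{PAMatrix} over all genomes.
#' @param graph optional \linkS4class{PangenomeGraph}; when given, subsets
#'   are partitioned by NEM on the induced graph (weights recomputed with
#'   the subset's N), otherwise by BinEM.
#' @param maxN largest subset size (default 100).
#' @param reps replicates per size (default 30).
#' @param seed RNG seed.
#' @param partitionMode "reselect", "fixed" or "none".
#' @param KFull number of partitions found on the full data (required
#'   unless partitionMode = "none"); the per-subset grid is 3..KFull.
#' @param beta,maxDegree NEM controls.
#' @param minNFit smallest subset size used in Heaps' fits (default 16).
#' @param softThreshold soft-core presence fraction.
#' @return a \linkS4class{RarefactionResult}.
#' @export
rarefactionCurves <- function(X, graph = NULL, maxN = 100, reps = 30,
                              seed = NULL,
                              partitionMode = c("reselect", "fixed",
                                                "none"),
                              KFull = NULL, beta = 2.5, maxDegree = 10,
                              minNFit = 16, softThreshold = 0.95) {
  partitionMode <- match.arg(partitionMode)
  if (reps < 1) stop("reps must be >= 1")
  gens <- genomeNames(X)
  N <- length(gens)
  if (N < 2) stop("rarefaction needs at least 2 genomes")
  if (partitionMode != "none" && is.null(KFull))
    stop("KFull is required unless partitionMode = 'none'")
  if (!is.null(seed)) set.seed(seed)
  sizes <- seq_len(min(maxN, N))

  rows <- vector("list", length(sizes) * reps)
  idx <- 0L
  for (n in sizes) {
    for (r in seq_len(reps)) {
      sub <- sample(gens, n)
      Xs <- X[, sub]
      part <- NULL
      if (partitionMode != "none") {
        Fs <- nrow(Xs)
        K <- if (partitionMode == "fixed") min(KFull, Fs) else {
          grid <- 3:KFull
          grid <- grid[grid <= Fs]
          if (length(grid)) selectK(Xs, KGrid = grid)@KHat else NA_integer_
        }
        if (!is.na(K) && K >= 2 && K <= Fs) {
          gs <- if (!is.null(graph))
            subsetGraphGenomes(graph, sub, keepFamilies = familyNames(Xs))
          else NULL
          part <- runNEM(Xs, gs, K = K, beta = beta,
                         maxDegree = maxDegree)$partitioning
        }
      }
      cc <- componentCounts(Xs, part, softThreshold)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(component = names(cc), n = n, rep = r,
                                count = as.numeric(cc))
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL

  quart <- do.call(rbind, lapply(split(
    samples, list(samples$component, samples$n), drop = TRUE),
    function(d) {
      q <- stats::quantile(d$count, c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
      data.frame(component = d$component[1], n = d$n[1],
                 q1 = q[1], median = q[2], q3 = q[3])
    }))
  quart <- quart[order(quart$component, quart$n), ]
  rownames(quart) <- NULL

  heaps <- do.call(rbind, lapply(RAREFACTION_COMPONENTS, function(cp) {
    d <- samples[samples$component == cp & !is.na(samples$count), ]
    fit <- tryCatch(fitHeaps(d[c("n", "count")], minNFit = minNFit),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(component = cp, kappa = NA_real_,
                        gamma = NA_real_, se_kappa = NA_real_,
                        se_gamma = NA_real_, converged = FALSE))
    data.frame(component = cp, kappa = fit$kappa, gamma = fit$gamma,
               se_kappa = fit$se_kappa, se_gamma = fit$se_gamma,
               converged = fit$converged)
  }))

  areas <- vapply(RAREFACTION_COMPONENTS, function(cp) {
    q <- quart[quart$component == cp & !is.na(quart$q1), ]
    if (nrow(q) < 2) return(NA_real_)
    iqrArea(q)
  }, numeric(1))

  new("RarefactionResult", samples = samples, quartiles = quart,
      heaps = heaps, iqrArea = areas, reps = as.integer(reps),
      maxN = as.integer(max(sizes)))
}

#' Fit Heaps' law to rarefaction points
#'
#' Nonlinear least squares (Levenberg-Marquardt) of count = kappa * n^gamma
#' on all replicate points with n >= \code{minNFit}; smaller subsets are
#' too variable and excluded. Start values: kappa = mean count at the
#' smallest fitted size, gamma = 0. gamma is the growth tendency of the
#' component (0 = closed, larger = more open).
#'
#' @param points data.frame with columns \code{n}, \code{count} (replicate
#'   points, not medians).
#' @param minNFit smallest n included (default 16, i.e. sizes <= 15
#'   excluded).
#' @return list with \code{kappa}, \code{gamma}, \code{se_kappa},
#'   \code{se_gamma}, \code{converged}; standard errors are NaN when the
#'   fit fails to converge.
#' @export
fitHeaps <- function(points, minNFit = 16) {
  d <- points[points$n >= minNFit & !is.na(points$count), , drop = FALSE]
  if (length(unique(d$n)) < 3)
    stop("need at least 3 distinct subset sizes >= minNFit")
  if (all(d$count == 0)) stop("all counts are zero")
  k0 <- mean(d$count[d$n == min(d$n)])
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ kappa * n^gamma, data = d,
                      start = list(kappa = k0, gamma = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(kappa = NA_real_, gamma = NA_real_, se_kappa = NaN,
                se_gamma = NaN, converged = FALSE))
  co <- summary(fit)$coefficients
  list(kappa = co["kappa", "Estimate"], gamma = co["gamma", "Estimate"],
       se_kappa = co["kappa", "Std. Error"],
       se_gamma = co["gamma", "Std. Error"], converged = TRUE)
}

#' Interquartile ribbon area of a rarefaction curve
#'
#' Trapezoidal integral of Q3(n) - Q1(n) over the sampled sizes; a
#' stability measure of the component estimate under resampling.
#'
#' @param quartiles data.frame with columns \code{n}, \code{q1}, \code{q3}
#'   (one row per size).
#' @return the area (numeric).
#' @export
iqrArea <- function(quartiles) {
  q <- quartiles[order(quartiles$n), ]
  if (nrow(q) < 2) stop("need quartiles at >= 2 sizes")
  w <- q$q3 - q$q1
  sum((w[-1] + w[-length(w)]) / 2 * diff(q$n))
}
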