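# Cache for the label-correlation calibration: the calibration is a
# deterministic function of the targets (it uses its own fixed
# common-random-number stream), so it is solved once per configuration.
.calibration_cache <- new.env(parent = emptyenv())

# Fixed orthonormal 5 x 5 sign pattern (no small entries). Each descriptor
# group feeds all five endpoint factors through one column each, so every
# informative descriptor matters for every endpoint, while the factors
# stay exactly uncorrelated (columns are orthogonal, so the cross terms
# cancel). Re-orthonormalized at load to remove rounding drift.
admet_pattern <- function() {
  m <- matrix(c(
    -0.448843, -0.616842,  0.402419,  0.396441,  0.314130,
    -0.356053, -0.537706, -0.438274, -0.479875, -0.400643,
     0.464426, -0.349436, -0.355855, -0.212758,  0.700186,
    -0.616183,  0.404920, -0.527713,  0.158880,  0.389740,
    -0.276558,  0.206813,  0.491268, -0.735843,  0.312532), 5, 5)
  q <- qr.Q(qr(m))
  q * sign(diag(crossprod(q, m)))[col(q)]  # keep the recorded orientation
}

#' Configuration of the synthetic QSAR benchmark generator
#'
#' The defaults emulate the shape and difficulty of a realistic
#' descriptor-table screening campaign: ~2,000 compounds, several hundred
#' correlated-scale 2-D descriptors of which a small subset drives a
#' continuous pIC50 nonlinearly, a block of all-zero descriptors (as
#' produced by descriptor software on structure classes lacking a
#' substructure), and five binary ADMET endpoints with realistic
#' class imbalance and a planted inter-endpoint phi-association
#' structure.
#'
#' @param n_compounds labeled compounds.
#' @param n_descriptors total descriptor columns (including the all-zero
#'   block).
#' @param n_informative_activity descriptors driving pIC50.
#' @param n_informative_admet size of the ADMET-informative descriptor
#'   pool (shared across the five endpoints; must be divisible by 5).
#' @param n_constant_zero all-zero descriptor columns.
#' @param noise_sd Gaussian noise on pIC50, in pIC50 units.
#' @param high_activity_fraction fraction of compounds with pIC50 above
#'   the activity gate at 6.
#' @param admet_prevalences named positive-class rates of the five
#'   endpoints, in (0, 1).
#' @param latent_correlation 5 x 5 symmetric target phi matrix (unit
#'   diagonal) for the endpoint labels.
#' @param signal_scale strength of the descriptor-driven component of the
#'   ADMET liabilities (standard deviations per unit score).
#' @param latent_loading loading of the shared latent factor that couples
#'   endpoints beyond their descriptor overlap.
#' @param logistic_scale scale of the logistic noise on each liability.
#' @param n_unlabeled extra unlabeled compounds (descriptors emitted, true
#'   activity recorded only in the ground truth) for screening exercises.
#' @param seed integer seed; every downstream draw fans out from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 2000L, n_descriptors = 500L,
                             n_informative_activity = 10L,
                             n_informative_admet = 40L,
                             n_constant_zero = 10L,
                             noise_sd = 0.4,
                             high_activity_fraction = 0.62,
                             admet_prevalences = c("Caco-2" = 0.30,
                                                   "CYP3A4" = 0.80,
                                                   "hERG" = 0.65,
                                                   "HOB" = 0.15,
                                                   "MN" = 0.70),
                             latent_correlation = default_phi_targets(),
                             signal_scale = 6, latent_loading = 0.5,
                             logistic_scale = 0.4,
                             n_unlabeled = 0L, seed = 1L) {
  stopifnot(n_informative_activity <= n_descriptors - n_constant_zero,
            n_informative_admet <= n_descriptors - n_constant_zero,
            n_informative_admet %% 5L == 0L,
            n_constant_zero < n_descriptors,
            noise_sd > 0, logistic_scale > 0,
            high_activity_fraction > 0, high_activity_fraction < 1)
  if (length(admet_prevalences) != 5L ||
      any(admet_prevalences <= 0) || any(admet_prevalences >= 1))
    stop("admet_prevalences must be five rates in (0, 1)")
  if (is.null(names(admet_prevalences)))
    names(admet_prevalences) <- ADMET_PROPERTIES
  lc <- as.matrix(latent_correlation)
  if (!isTRUE(all.equal(lc, t(lc))) || any(diag(lc) != 1))
    stop("latent_correlation must be symmetric with unit diagonal")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative_activity = as.integer(n_informative_activity),
                 n_informative_admet = as.integer(n_informative_admet),
                 n_constant_zero = as.integer(n_constant_zero),
                 noise_sd = noise_sd,
                 high_activity_fraction = high_activity_fraction,
                 admet_prevalences = admet_prevalences,
                 latent_correlation = lc,
                 signal_scale = signal_scale,
                 latent_loading = latent_loading,
                 logistic_scale = logistic_scale,
                 n_unlabeled = as.integer(n_unlabeled),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default target phi matrix of the five ADMET endpoints
#'
#' The dominant association structure of the endpoints: permeability
#' anti-associated with metabolism and cardiotoxicity liabilities,
#' associated with oral bioavailability; metabolism and cardiotoxicity
#' positively associated; genotoxicity independent of the rest.
#'
#' @return 5 x 5 symmetric matrix.
#' @export
default_phi_targets <- function() {
  m <- diag(5)
  dimnames(m) <- list(ADMET_PROPERTIES, ADMET_PROPERTIES)
  m["Caco-2", "CYP3A4"] <- m["CYP3A4", "Caco-2"] <- -0.39
  m["Caco-2", "hERG"] <- m["hERG", "Caco-2"] <- -0.44
  m["Caco-2", "HOB"] <- m["HOB", "Caco-2"] <- 0.29
  m["CYP3A4", "hERG"] <- m["hERG", "CYP3A4"] <- 0.55
  m["CYP3A4", "HOB"] <- m["HOB", "CYP3A4"] <- -0.18
  m["hERG", "HOB"] <- m["HOB", "hERG"] <- -0.23
  m
}

# Attainable phi range for two binaries with the given prevalences
# (Frechet bounds).
phi_bounds <- function(p1, p2) {
  q1 <- 1 - p1; q2 <- 1 - p2
  c(lower = max(-sqrt(p1 * p2 / (q1 * q2)), -sqrt(q1 * q2 / (p1 * p2))),
    upper = min(sqrt(p1 * q2 / (p2 * q1)), sqrt(p2 * q1 / (p1 * q2))))
}

# Solve, by common-random-number Monte Carlo and pairwise 1-D root
# finding, the correlation matrix of the descriptor-driven endpoint
# scores that realizes the target label phi matrix under the liability
# model z = signal_scale * g + latent_loading * u + logistic noise.
calibrate_label_correlation <- function(prev, phi_target, gamma, lam, ls,
                                        m = 100000L) {
  key <- paste(c(prev, phi_target, gamma, lam, ls, m), collapse = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  k <- length(prev)
  draws <- with_seed(20260928L, list(
    f = rnorm(m), h1 = rnorm(m), h2 = rnorm(m), u = rnorm(m),
    e1 = rlogis(m), e2 = rlogis(m), z = rnorm(m), e = rlogis(m)))
  # marginal thresholds of z = gamma*N(0,1) + lam*u + ls*logistic
  z_marg <- gamma * draws$z + lam * draws$u + ls * draws$e
  thresholds <- vapply(prev, function(p) quantile(z_marg, 1 - p, names = FALSE),
                       numeric(1))
  phi_of_c <- function(cc, i, j) {
    a <- sign(cc) * sqrt(abs(cc))
    b <- sqrt(abs(cc))
    gi <- a * draws$f + sqrt(1 - abs(cc)) * draws$h1
    gj <- b * draws$f + sqrt(1 - abs(cc)) * draws$h2
    zi <- gamma * gi + lam * draws$u + ls * draws$e1
    zj <- gamma * gj + lam * draws$u + ls * draws$e2
    yi <- zi > thresholds[i]; yj <- zj > thresholds[j]
    n11 <- sum(yi & yj); n10 <- sum(yi & !yj)
    n01 <- sum(!yi & yj); n00 <- sum(!yi & !yj)
    num <- as.numeric(n11) * n00 - as.numeric(n10) * n01
    den <- sqrt(as.numeric(n11 + n10) * (n01 + n00) *
                as.numeric(n11 + n01) * (n10 + n00))
    if (den == 0) return(NA_real_)
    num / den
  }
  C <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    target <- phi_target[i, j]
    bounds <- phi_bounds(prev[i], prev[j])
    if (target < bounds["lower"] || target > bounds["upper"])
      stop(sprintf("target phi %.3f for pair (%s, %s) is infeasible for prevalences %.2f/%.2f",
                   target, names(prev)[i], names(prev)[j], prev[i], prev[j]))
    lo <- phi_of_c(-0.999, i, j); hi <- phi_of_c(0.999, i, j)
    if (target < lo || target > hi)
      stop(sprintf("target phi %.3f for pair (%s, %s) is outside the mechanism's attainable range [%.3f, %.3f]",
                   target, names(prev)[i], names(prev)[j], lo, hi))
    C[i, j] <- C[j, i] <- uniroot(function(cc) phi_of_c(cc, i, j) - target,
                                  c(-0.999, 0.999), tol = 1e-3)$root
  }
  # nearest-PSD projection (eigenvalue clipping + unit-diagonal rescale)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    C <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
  }
  out <- list(C = C, thresholds = thresholds)
  .calibration_cache[[key]] <- out
  out
}

#' Generate a synthetic QSAR screening dataset with recorded ground truth
#'
#' Emits a descriptor matrix, a continuous activity table and five binary
#' ADMET labels with planted, fully known structure:
#' \itemize{
#'   \item descriptors on deliberately mixed scales (to exercise min-max
#'     normalization) including a block of all-zero columns (to exercise
#'     the uninformative-descriptor filter);
#'   \item pIC50 = scaled additive effects of the informative subset, one
#'     pairwise interaction and one threshold effect, plus Gaussian
#'     noise, shifted so a stated fraction of compounds exceeds the
#'     activity gate at 6;
#'   \item ADMET labels from thresholded liabilities combining
#'     descriptor-driven scores (built on an informative pool shared
#'     across endpoints, with score correlations calibrated to the target
#'     phi matrix), a shared latent factor, and logistic noise.
#' }
#' Fully reproducible: the same configuration yields bit-identical
#' output.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `descriptors` ([descriptor_matrix()]), `activity`
#'   (data.frame `compound_id`, `pic50`), `admet` (data.frame
#'   `compound_id` + five 0/1 columns), `unlabeled` (descriptor matrix or
#'   `NULL`), and `ground_truth` (informative sets, generating
#'   coefficients, realized phi matrix and prevalences, and every
#'   calibration constant).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) stop("cfg must be a synthetic_config")
  prev <- cfg$admet_prevalences
  cal <- calibrate_label_correlation(prev, cfg$latent_correlation,
                                     cfg$signal_scale, cfg$latent_loading,
                                     cfg$logistic_scale)
  with_seed(cfg$seed, {
    n <- cfg$n_compounds + cfg$n_unlabeled
    p <- cfg$n_descriptors
    p_eff <- p - cfg$n_constant_zero
    ids <- sprintf("CPD%05d", seq_len(n))
    Z <- matrix(rnorm(n * p_eff), n, p_eff)

    # --- activity -------------------------------------------------------
    k_act <- cfg$n_informative_activity
    act_idx <- sample.int(p_eff, k_act)
    beta <- seq(1.2, 0.6, length.out = k_act) * rep_len(c(1, -1), k_act)
    s <- as.vector(Z[, act_idx, drop = FALSE] %*% beta)
    if (k_act >= 2L) s <- s + 0.6 * Z[, act_idx[1]] * Z[, act_idx[2]]
    if (k_act >= 3L) s <- s + 0.8 * (Z[, act_idx[3]] > 0.5)
    act_scale <- 1.15 / sd(s)
    s <- s * act_scale
    pic50 <- s + rnorm(n, 0, cfg$noise_sd)
    act_shift <- 6 - quantile(pic50, 1 - cfg$high_activity_fraction,
                              names = FALSE)
    pic50 <- pic50 + act_shift

    # --- ADMET ----------------------------------------------------------
    k_adm <- cfg$n_informative_admet
    n_shared <- min(5L, k_act)
    pool_idx <- c(act_idx[seq_len(n_shared)],
                  sample(setdiff(seq_len(p_eff), act_idx), k_adm - n_shared))
    pool_idx <- sample(pool_idx)  # shuffle so groups mix shared/fresh
    n_groups <- k_adm / 5L
    groups <- split(pool_idx, rep(seq_len(n_groups), each = 5L))
    # every group feeds every factor (through one orthogonal pattern
    # column each) with geometrically decaying strength, so each factor
    # has one dominant 5-descriptor group yet all pool descriptors are
    # informative for all endpoints; factors are exactly uncorrelated
    pattern <- admet_pattern()
    Fmat <- sapply(1:5, function(k) {
      decay <- 0.5^((seq_len(n_groups) - k) %% n_groups)
      f <- numeric(n)
      for (g in seq_len(n_groups))
        f <- f + decay[g] *
          as.vector(Z[, groups[[g]], drop = FALSE] %*% pattern[, k])
      f / sqrt(sum(decay^2))
    })
    # symmetric square root: order-invariant loading of factors onto
    # endpoints (Corr(G) = L L' = C for any root; this one treats the
    # five endpoints symmetrically)
    ev <- eigen(cal$C, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    G <- Fmat %*% t(L)  # endpoint scores with Corr ~= calibrated C
    u <- rnorm(n)
    labels <- matrix(0L, n, 5L, dimnames = list(ids, names(prev)))
    for (j in 1:5) {
      z <- cfg$signal_scale * G[, j] + cfg$latent_loading * u +
        cfg$logistic_scale * rlogis(n)
      labels[, j] <- as.integer(z > cal$thresholds[j])
    }

    # --- emission: mixed scales, zero block, shuffled columns ----------
    desc_names <- sprintf("D%04d", seq_len(p))
    scale_kind <- sample(1:3, p_eff, replace = TRUE, prob = c(.4, .4, .2))
    mu <- ifelse(scale_kind == 1, runif(p_eff, -2, 2), runif(p_eff, 5, 200))
    sdv <- ifelse(scale_kind == 1, runif(p_eff, 0.5, 2), runif(p_eff, 2, 40))
    X <- sweep(sweep(Z, 2, sdv, "*"), 2, mu, "+")
    informative <- union(act_idx, pool_idx)
    logcols <- which(scale_kind == 3 & !(seq_len(p_eff) %in% informative))
    X[, logcols] <- exp(Z[, logcols, drop = FALSE])  # skewed noise columns
    zero_pos <- sort(sample.int(p, cfg$n_constant_zero))
    eff_pos <- setdiff(seq_len(p), zero_pos)
    full <- matrix(0, n, p, dimnames = list(ids, desc_names))
    full[, eff_pos] <- X
    eff_name <- desc_names[eff_pos]  # name of each core column

    labeled <- seq_len(cfg$n_compounds)
    unlab <- if (cfg$n_unlabeled > 0L) (cfg$n_compounds + 1L):n else integer(0)

    realized_phi <- phi_association_matrix(labels[labeled, , drop = FALSE])
    ground_truth <- list(
      informative_activity = eff_name[act_idx],
      activity_coefficients = setNames(beta * act_scale, eff_name[act_idx]),
      activity_interaction = if (k_act >= 2L)
        c(eff_name[act_idx[1]], eff_name[act_idx[2]]) else NULL,
      activity_threshold_descriptor = if (k_act >= 3L)
        eff_name[act_idx[3]] else NULL,
      activity_scale = act_scale, activity_shift = act_shift,
      admet_pool = eff_name[pool_idx],
      admet_groups = lapply(groups, function(gi) eff_name[gi]),
      admet_dominant_group = lapply(1:5, function(k)
        eff_name[groups[[((k - 1L) %% n_groups) + 1L]]]),
      score_loadings = L, solved_score_correlation = cal$C,
      target_phi = cfg$latent_correlation,
      realized_phi = realized_phi$phi,
      realized_prevalences = colMeans(labels[labeled, , drop = FALSE]),
      realized_high_fraction = mean(pic50[labeled] >= 6),
      thresholds = cal$thresholds,
      constant_zero_descriptors = desc_names[zero_pos],
      unlabeled_true_pic50 = if (length(unlab))
        setNames(pic50[unlab], ids[unlab]) else NULL,
      seed = cfg$seed)

    list(descriptors = descriptor_matrix(full[labeled, , drop = FALSE]),
         activity = data.frame(compound_id = ids[labeled],
                               pic50 = pic50[labeled],
                               stringsAsFactors = FALSE),
         admet = data.frame(compound_id = ids[labeled],
                            labels[labeled, , drop = FALSE],
                            check.names = FALSE, stringsAsFactors = FALSE),
         unlabeled = if (length(unlab))
           descriptor_matrix(full[unlab, , drop = FALSE]) else NULL,
         ground_truth = ground_truth)
  })
}

#' Write the small fixed fixture files used across the test surface
#'
#' Emits tiny, fully deterministic CSV fixtures (a 3 x 4 descriptor
#' table, activity and ADMET label tables, a worked-example prediction
#' pair, a 2 x 2 contingency table) plus a JSON manifest with MD5
#' checksums. Running it twice produces identical files.
#'
#' @param out_dir writable output directory (created if missing).
#' @return data.frame manifest (`file`, `md5`), invisibly written to
#'   `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stop("directory not writable: ", out_dir)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(
    wr(data.frame(Name = c("CPD1", "CPD2", "CPD3"),
                  ALogP = c(1.2, -0.4, 3.3), TPSA = c(20.3, 88.1, 45.0),
                  nRing = c(1, 3, 2), ZeroD = c(0, 0, 0),
                  check.names = FALSE), "tiny_descriptors.csv"),
    wr(data.frame(Name = c("CPD1", "CPD2", "CPD3"),
                  pIC50 = c(6.5, 5.1, 7.3)), "tiny_activity.csv"),
    wr(setNames(data.frame(c("CPD1", "CPD2", "CPD3"), c(1, 0, 1), c(1, 1, 0),
                           c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
                c("Name", ADMET_PROPERTIES)), "tiny_admet.csv"),
    wr(data.frame(y_true = c(2, 4), y_pred = c(1, 5)),
       "worked_regression_pair.csv"),
    wr(data.frame(n11 = 40, n10 = 10, n01 = 10, n00 = 40),
       "worked_contingency.csv"),
    wr(data.frame(label = c(0, 0, 1, 1), score = c(0.1, 0.4, 0.35, 0.8)),
       "worked_auc.csv"))
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows")
  manifest
}
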