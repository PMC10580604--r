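# Synthetic cohort generator. Geometry is designed so the area-feature
# extractor provably recovers ground truth: tumor blobs are isolated solid
# squares (invariant under 5x5 closing when kept >= 2 cells from the grid
# border), inside-lymphocytes occupy a stride-2 interior sub-lattice (each a
# single-cell hole that closing refills), around-lymphocytes sit in the
# Chebyshev <= band ring, and stroma regions are isolated rectangles.

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: grid size, tumor blob
#' geometry, lymphocyte placement rates inside and around tumors, stroma
#' coverage, the proportional-hazards link from planted area features to
#' survival, and the censoring rate.
#'
#' When `tumor_blobs` is `NULL` (default) each patient receives a random
#' number of blobs with random radii drawn from `n_blobs_range` and
#' `radius_range`, so planted features vary across the cohort and
#' `hazard_betas` carries signal. A fixed list of blob specs
#' (`list(list(row=, col=, radius=), ...)`) may be given instead for
#' deterministic maps.
#'
#' `hazard_betas` are coefficients on the cohort-standardized planted
#' features, in canonical order: max tumor area, lymphocytes inside, around,
#' the (around+1)/(inside+1) ratio, total stroma area. The default signs
#' follow the prognostic directions reported for colorectal cohorts (larger
#' tumors, more intratumoral lymphocytes and more stroma: worse; more
#' peritumoral lymphocytes and a larger ratio: better).
#'
#' @param n_patients number of patients.
#' @param map_rows,map_cols grid of patch positions.
#' @param tumor_blobs optional fixed list of blob specs (see Details).
#' @param n_blobs_range,radius_range integer ranges sampled per patient when
#'   `tumor_blobs` is NULL. Radii are Chebyshev radii: radius r gives a
#'   (2r+1) x (2r+1) square blob; radius 0 is a single cell.
#' @param lym_inside_rate,lym_around_rate per-candidate-cell lymphocyte
#'   placement probabilities in `[0, 1]`.
#' @param stroma_fraction target fraction of grid cells covered by stroma.
#' @param patch_pixels synthetic patch edge length in pixels.
#' @param hazard_betas named or positional numeric length 5 (see Details).
#' @param censor_rate target censoring probability in `[0, 1]`.
#' @param texture_noise_sd pixel noise of the patch texture model.
#' @param texture_hazard_coef brightness shift per unit standardized
#'   log-hazard applied to a patient's patches (0 = textures carry no
#'   survival signal).
#' @param seed integer cohort seed; all stages derive from it.
#' @return list of class `syntheticCohortConfig`.
#' @export
syntheticCohortConfig <- function(n_patients = 100L,
                                  map_rows = 32L, map_cols = 32L,
                                  tumor_blobs = NULL,
                                  n_blobs_range = c(1L, 2L),
                                  radius_range = c(2L, 5L),
                                  lym_inside_rate = 0.25,
                                  lym_around_rate = 0.25,
                                  stroma_fraction = 0.08,
                                  patch_pixels = 32L,
                                  hazard_betas = c(
                                    max_tumor_area = 1.0,
                                    lymphocyte_inside_tumor = 0.5,
                                    lymphocyte_around_tumor = -0.5,
                                    around_inside_ratio = -0.5,
                                    total_stroma_area = 0.5),
                                  censor_rate = 0.2,
                                  texture_noise_sd = 0.08,
                                  texture_hazard_coef = 0,
                                  seed = 1L) {
  probs <- c(lym_inside_rate, lym_around_rate, stroma_fraction, censor_rate)
  if (any(probs < 0 | probs > 1))
    stop("rates and fractions must lie in [0, 1]")
  if (n_patients < 1L || map_rows < 2L || map_cols < 2L)
    stop("n_patients must be >= 1 and map dimensions >= 2")
  if (!is.null(tumor_blobs)) {
    for (b in tumor_blobs) {
      if (b$radius < 0L) stop("blob radius must be >= 0")
    }
  } else {
    if (any(radius_range < 0L)) stop("blob radius must be >= 0")
    if (min(map_rows, map_cols) < 2L * max(radius_range))
      stop("map dimensions must be at least twice the maximal blob radius")
  }
  if (length(hazard_betas) != 5L || any(!is.finite(hazard_betas)))
    stop("hazard_betas must be 5 finite coefficients")
  structure(list(
    n_patients = as.integer(n_patients),
    map_rows = as.integer(map_rows), map_cols = as.integer(map_cols),
    tumor_blobs = tumor_blobs,
    n_blobs_range = as.integer(n_blobs_range),
    radius_range = as.integer(radius_range),
    lym_inside_rate = lym_inside_rate, lym_around_rate = lym_around_rate,
    stroma_fraction = stroma_fraction,
    patch_pixels = as.integer(patch_pixels),
    hazard_betas = hazard_betas, censor_rate = censor_rate,
    texture_noise_sd = texture_noise_sd,
    texture_hazard_coef = texture_hazard_coef,
    seed = as.integer(seed)), class = "syntheticCohortConfig")
}

# Chebyshev-gap between the bounding squares of two blobs
.blobGap <- function(a, b) {
  max(abs(a$row - b$row), abs(a$col - b$col)) - a$radius - b$radius
}

# sample per-patient blob specs honoring margins and separation
.sampleBlobs <- function(cfg) {
  nb <- if (cfg$n_blobs_range[1] == cfg$n_blobs_range[2]) cfg$n_blobs_range[1]
        else sample(cfg$n_blobs_range[1]:cfg$n_blobs_range[2], 1L)
  blobs <- list()
  margin <- 4L  # 2 for closing border effects + 2 for the around band
  for (i in seq_len(nb)) {
    r <- if (cfg$radius_range[1] == cfg$radius_range[2]) cfg$radius_range[1]
         else sample(cfg$radius_range[1]:cfg$radius_range[2], 1L)
    placed <- FALSE
    for (try in 1:200) {
      lo_r <- margin + r + 1L; hi_r <- cfg$map_rows - margin - r
      lo_c <- margin + r + 1L; hi_c <- cfg$map_cols - margin - r
      if (lo_r > hi_r || lo_c > hi_c) break
      cand <- list(row = sample(lo_r:hi_r, 1L), col = sample(lo_c:hi_c, 1L),
                   radius = r)
      if (all(vapply(blobs, function(b) .blobGap(cand, b) >= 6L, logical(1)))) {
        blobs[[length(blobs) + 1L]] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed && r > cfg$radius_range[1]) {
      # retry once with the smallest radius before giving up on this blob
      i <- i  # no-op; smaller blobs are attempted on later iterations anyway
    }
  }
  blobs
}

.validateBlobs <- function(blobs, cfg) {
  for (b in blobs) {
    if (b$row - b$radius < 1L || b$row + b$radius > cfg$map_rows ||
        b$col - b$radius < 1L || b$col + b$radius > cfg$map_cols)
      stop(sprintf("blob at (%d,%d) radius %d out of grid bounds",
                   b$row, b$col, b$radius))
  }
  blobs
}

#' Generate one patient's tissue map with ground truth
#'
#' Plants solid square tumor blobs, replaces a stride-2 interior sub-lattice
#' of blob cells with lymphocytes at rate `lym_inside_rate`, places
#' lymphocytes in the Chebyshev distance 1..2 ring around each blob at rate
#' `lym_around_rate`, adds isolated stroma rectangles up to
#' `stroma_fraction`, and fills the remainder with a mix of the other
#' classes. Ground truth records both raw cell counts (recountable on the
#' emitted map) and the feature-level truths (closed-mask areas) the
#' area-feature stage recovers.
#'
#' @param cfg a [syntheticCohortConfig()].
#' @param patient_index 1-based patient index (`<= n_patients`).
#' @return list with elements `map` (a [TissueMap-class]) and `truth`
#'   (one-row data.frame).
#' @export
generateTissueMap <- function(cfg, patient_index) {
  stopifnot(inherits(cfg, "syntheticCohortConfig"))
  if (patient_index < 1L || patient_index > cfg$n_patients)
    stop("patient_index out of range")
  .withSeed(deriveSeed(cfg$seed, paste0("map:", patient_index)), {
    nr <- cfg$map_rows; nc <- cfg$map_cols
    other <- c("NORM", "ADI", "DEB", "MUS", "MUC", "BACK")
    pOther <- c(0.45, 0.10, 0.08, 0.12, 0.15, 0.10)
    labels <- matrix(sample(other, nr * nc, replace = TRUE, prob = pOther),
                     nr, nc)
    blobs <- if (is.null(cfg$tumor_blobs)) .sampleBlobs(cfg)
             else .validateBlobs(cfg$tumor_blobs, cfg)
    inside <- 0L; around <- 0L; blobAreas <- integer()
    for (b in blobs) {
      rs <- (b$row - b$radius):(b$row + b$radius)
      cs <- (b$col - b$radius):(b$col + b$radius)
      labels[rs, cs] <- "TUM"
      blobAreas <- c(blobAreas, length(rs) * length(cs))
      # inside lymphocytes: strict-interior stride-2 sub-lattice
      if (b$radius >= 1L && cfg$lym_inside_rate > 0) {
        ir <- rs[rs > min(rs) & rs < max(rs)]
        ic <- cs[cs > min(cs) & cs < max(cs)]
        ir <- ir[(ir - b$row) %% 2L == 0L]
        ic <- ic[(ic - b$col) %% 2L == 0L]
        for (i in ir) for (j in ic) {
          if (runif(1) < cfg$lym_inside_rate) {
            labels[i, j] <- "LYM"
            inside <- inside + 1L
          }
        }
      }
      # around lymphocytes: Chebyshev distance 1..2 ring
      if (cfg$lym_around_rate > 0) {
        for (d in 1:2) {
          rr <- (b$row - b$radius - d):(b$row + b$radius + d)
          cc <- (b$col - b$radius - d):(b$col + b$radius + d)
          ring <- rbind(
            cbind(rr[1], cc), cbind(rr[length(rr)], cc),
            cbind(rr[-c(1, length(rr))], cc[1]),
            cbind(rr[-c(1, length(rr))], cc[length(cc)]))
          for (k in seq_len(nrow(ring))) {
            i <- ring[k, 1]; j <- ring[k, 2]
            if (i >= 1L && i <= nr && j >= 1L && j <= nc &&
                runif(1) < cfg$lym_around_rate) {
              labels[i, j] <- "LYM"
              around <- around + 1L
            }
          }
        }
      }
    }
    # stroma rectangles: margin 2 from border, Chebyshev gap >= 5 from blob
    # squares and from each other so closing leaves each rectangle unchanged
    strTarget <- .roundHalfUp(cfg$stroma_fraction * nr * nc)
    strCells <- 0L
    strRects <- list()
    tries <- 0L
    while (strCells < strTarget && tries < 300L) {
      tries <- tries + 1L
      h <- sample(2:6, 1L); w <- sample(2:6, 1L)
      if (nr - h - 1L < 3L || nc - w - 1L < 3L) break
      r0 <- sample(3:(nr - h - 1L), 1L); c0 <- sample(3:(nc - w - 1L), 1L)
      rect <- list(r0 = r0, c0 = c0, r1 = r0 + h - 1L, c1 = c0 + w - 1L)
      okBlob <- all(vapply(blobs, function(b) {
        dr <- max(b$row - b$radius - rect$r1, rect$r0 - (b$row + b$radius), 0L)
        dc <- max(b$col - b$radius - rect$c1, rect$c0 - (b$col + b$radius), 0L)
        max(dr, dc) >= 6L
      }, logical(1)))
      okRect <- all(vapply(strRects, function(s) {
        dr <- max(s$r0 - rect$r1, rect$r0 - s$r1, 0L)
        dc <- max(s$c0 - rect$c1, rect$c0 - s$c1, 0L)
        max(dr, dc) >= 6L
      }, logical(1)))
      if (okBlob && okRect) {
        labels[rect$r0:rect$r1, rect$c0:rect$c1] <- "STR"
        strRects[[length(strRects) + 1L]] <- rect
        strCells <- strCells + h * w
      }
    }
    maxTumor <- if (length(blobAreas)) max(blobAreas) else 0L
    truth <- data.frame(
      patient_id = sprintf("P%04d", patient_index),
      n_blobs = length(blobs),
      tum_cells = sum(labels == "TUM"),
      lym_cells = sum(labels == "LYM"),
      str_cells = strCells,
      max_tumor_area = maxTumor,
      lymphocyte_inside_tumor = inside,
      lymphocyte_around_tumor = around,
      around_inside_ratio = (around + 1) / (inside + 1),
      total_stroma_area = strCells,
      stringsAsFactors = FALSE)
    list(map = TissueMap(labels, slideID = truth$patient_id,
                         patchSize = cfg$patch_pixels),
         truth = truth)
  })
}

#' Generate survival outcomes from planted features
#'
#' Event times follow an exponential proportional-hazards model with
#' baseline rate 1: the log-hazard is `betas` dotted with the
#' cohort-standardized planted features. Censoring is independent
#' `U(0, c)` with `c` solved numerically so that the expected censoring
#' fraction equals `censor_rate`; the realized rate is therefore within
#' sampling error of the target. `censor_rate = 1` is the degenerate
#' all-censored limit and is handled by censoring every patient strictly
#' before the event.
#'
#' @param truth ground-truth data.frame as produced by
#'   [generateTissueMap()] (one row per patient).
#' @param betas numeric length 5, coefficients on the five standardized
#'   features.
#' @param censor_rate target censoring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with columns patient_id, time, event (1 = death
#'   observed), and log_hazard.
#' @export
generateSurvival <- function(truth, betas, censor_rate, seed = 1L) {
  if (censor_rate < 0 || censor_rate > 1)
    stop("censor_rate must lie in [0, 1]")
  if (any(!is.finite(betas))) stop("betas must be finite")
  featCols <- c("max_tumor_area", "lymphocyte_inside_tumor",
                "lymphocyte_around_tumor", "around_inside_ratio",
                "total_stroma_area")
  X <- as.matrix(truth[, featCols])
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0 | !is.finite(attr(Xs, "scaled:scale"))] <- 0
  Xs[!is.finite(Xs)] <- 0
  lp <- drop(Xs %*% as.numeric(betas))
  n <- nrow(truth)
  .withSeed(seed, {
    lambda <- exp(lp)
    tEvent <- rexp(n) / lambda
    if (censor_rate == 0) {
      time <- tEvent; event <- rep(1L, n)
    } else if (censor_rate >= 1) {
      time <- tEvent * runif(n); event <- rep(0L, n)
    } else {
      pcens <- function(cc) mean((1 - exp(-lambda * cc)) / (lambda * cc))
      f <- function(cc) pcens(cc) - censor_rate
      upper <- 1
      while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
      cmax <- uniroot(f, c(1e-9, upper))$root
      cens <- runif(n, 0, cmax)
      event <- as.integer(tEvent <= cens)
      time <- pmin(tEvent, cens)
    }
    data.frame(patient_id = truth$patient_id, time = time, event = event,
               log_hazard = lp, stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort
#'
#' Runs [generateTissueMap()] for every patient and [generateSurvival()] on
#' the pooled ground truth.
#'
#' @param cfg a [syntheticCohortConfig()].
#' @return a [SyntheticCohort-class].
#' @examples
#' co <- generateCohort(syntheticCohortConfig(n_patients = 3, seed = 7))
#' co
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticCohortConfig"))
  out <- lapply(seq_len(cfg$n_patients), function(i) generateTissueMap(cfg, i))
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(truth) <- NULL
  surv <- generateSurvival(truth, cfg$hazard_betas, cfg$censor_rate,
                           seed = deriveSeed(cfg$seed, "survival"))
  truth$log_hazard <- surv$log_hazard
  new("SyntheticCohort", maps = lapply(out, `[[`, "map"),
      groundTruth = truth,
      survival = surv[, c("patient_id", "time", "event")],
      config = unclass(cfg))
}
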