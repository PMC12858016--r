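#' Configuration for the synthetic EHR cohort generator
#'
#' Builds and validates the full parameterization of the regime-switching
#' synthetic cohort: a discrete clinical regime evolves per patient by a Markov
#' chain; within each regime a continuous latent state relaxes toward a
#' regime-specific anchor by overdamped Langevin (Ornstein-Uhlenbeck) updates;
#' coded laboratory items are emitted in \{0, 0.5, 1\} (abnormally low /
#' normal / abnormally high) with regime-dependent abnormality probabilities,
#' while anthropometric and vital items are emitted as continuous readouts of
#' the latent state. A patient carries a death flag iff the regime path ends
#' in `death_regime`.
#'
#' @param n_patients Number of patients to simulate.
#' @param n_items Number of emitted items (default 57: 2 anthropometric,
#'   1 gender, 4 vitals, 50 laboratory items).
#' @param n_regimes Number of discrete clinical regimes (default 3,
#'   mirroring stable / intermediate / dangerous states).
#' @param regime_transition_matrix Row-stochastic `n_regimes x n_regimes`
#'   matrix. Default is a sticky chain with 0.95 self-transition probability
#'   and an ordered drift toward neighbouring regimes.
#' @param abnormal_prob Numeric array `n_regimes x n_labs x 2` with
#'   `[, , 1]` = probability of an abnormally low code and `[, , 2]` =
#'   abnormally high, per regime and laboratory item; `low + high <= 1`
#'   cellwise. Default plants `n_planted` risky items whose abnormal-low
#'   probability rises steeply with regime severity while all other items are
#'   regime-independent.
#' @param n_planted Number of planted risky laboratory items used when
#'   `abnormal_prob` is left at its default.
#' @param death_regime Index (1-based) of the regime whose absorption at the
#'   final step marks death. Default `n_regimes`.
#' @param length_range Integer pair `(min_steps, max_steps)`; per-patient
#'   sequence lengths are sampled uniformly in this range (default c(50, 238),
#'   the retained clinical record lengths).
#' @param missing_rate Fraction of cells masked missing by [generate_cohort()]
#'   (applied through [apply_missingness()]); default 0.
#' @param missing_mechanism `"NCAR"` or `"MNAR"`.
#' @param mnar_mult Missingness probability multiplier for abnormal cells
#'   under MNAR (see [apply_missingness()]).
#' @param langevin List with `drift_strength`, `noise_scale`, `step_size` of
#'   the continuous latent updates, and `anchor_scale` for the spread of the
#'   regime anchors.
#' @param latent_dim Dimension of the continuous latent (default 8, matching
#'   the analysis latent space).
#' @param emission `"coded"` emits laboratory items directly on the coded
#'   \{0, 0.5, 1\} support; `"raw"` emits raw-valued labs around per-item
#'   reference ranges so that abnormal coding itself is exercised downstream.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_patients,
                         n_items = 57,
                         n_regimes = 3,
                         regime_transition_matrix = NULL,
                         abnormal_prob = NULL,
                         n_planted = 5,
                         death_regime = n_regimes,
                         length_range = c(50, 238),
                         missing_rate = 0,
                         missing_mechanism = c("NCAR", "MNAR"),
                         mnar_mult = 3,
                         langevin = list(drift_strength = 1, noise_scale = 0.35,
                                         step_size = 0.25, anchor_scale = 2),
                         latent_dim = 8,
                         emission = c("coded", "raw"),
                         seed = 1L) {
  stopifnot(is_count(n_patients), is_count(n_items), is_count(n_regimes),
            is_count(latent_dim))
  missing_mechanism <- match.arg(missing_mechanism)
  emission <- match.arg(emission)
  if (!(is.numeric(missing_rate) && length(missing_rate) == 1 &&
        missing_rate >= 0 && missing_rate < 1)) {
    abort("missing_rate must lie in [0, 1)")
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[1] > length_range[2]) {
    abort("length_range must be (min_steps, max_steps) with 1 <= min <= max")
  }
  if (!is_count(death_regime) || death_regime > n_regimes) {
    abort("death_regime out of range")
  }

  categories <- item_categories(n_items)
  n_labs <- sum(categories == "lab")

  if (is.null(regime_transition_matrix)) {
    regime_transition_matrix <- default_regime_matrix(n_regimes)
  }
  check_row_stochastic(regime_transition_matrix)

  if (is.null(abnormal_prob)) {
    abnormal_prob <- default_abnormal_prob(n_regimes, n_labs, n_planted)
  }
  if (!is.array(abnormal_prob) ||
      !all(dim(abnormal_prob) == c(n_regimes, n_labs, 2))) {
    abort("abnormal_prob must be an (n_regimes x n_labs x 2) array")
  }
  if (any(abnormal_prob < 0) || any(abnormal_prob > 1) ||
      any(abnormal_prob[, , 1] + abnormal_prob[, , 2] > 1 + 1e-12)) {
    abort("abnormal_prob entries must lie in [0,1] with low + high <= 1")
  }

  lang_defaults <- list(drift_strength = 1, noise_scale = 0.35,
                        step_size = 0.25, anchor_scale = 2)
  langevin <- utils::modifyList(lang_defaults, langevin)

  structure(list(
    n_patients = as.integer(n_patients), n_items = as.integer(n_items),
    n_regimes = as.integer(n_regimes),
    regime_transition_matrix = regime_transition_matrix,
    abnormal_prob = abnormal_prob,
    death_regime = as.integer(death_regime),
    length_range = length_range,
    missing_rate = missing_rate, missing_mechanism = missing_mechanism,
    mnar_mult = mnar_mult,
    langevin = langevin, latent_dim = as.integer(latent_dim),
    emission = emission, categories = categories,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Feature layout mirroring the clinical table: 2 anthropometric, 1 gender,
# 4 vitals, remaining items are coded labs.
item_categories <- function(n_items) {
  if (n_items < 8) return(rep("lab", n_items))
  c(rep("anthropometric", 2), "gender", rep("vital", 4),
    rep("lab", n_items - 7))
}

default_regime_matrix <- function(k) {
  P <- matrix(0, k, k)
  for (i in seq_len(k)) {
    P[i, i] <- 0.95
    rest <- setdiff(seq_len(k), i)
    # drift preferentially to adjacent severity levels
    w <- 1 / (abs(rest - i))
    P[i, rest] <- 0.05 * w / sum(w)
  }
  P
}

# Planted items get a steep regime gradient of abnormally-low probability
# (an anemia-like signature); the rest are regime-independent.
default_abnormal_prob <- function(n_regimes, n_labs, n_planted) {
  ap <- array(0, dim = c(n_regimes, n_labs, 2))
  ap[, , 1] <- 0.10
  ap[, , 2] <- 0.10
  n_planted <- min(n_planted, n_labs)
  if (n_planted > 0) {
    sev <- seq(0, 1, length.out = n_regimes)   # regime 1 mild .. k severe
    for (j in seq_len(n_planted)) {
      ap[, j, 1] <- 0.05 + 0.65 * sev
      ap[, j, 2] <- 0.05
    }
  }
  ap
}

#' Items whose abnormality profile separates regimes most
#'
#' Computes, per laboratory item, the ground-truth between-regime spread: the
#' sum over regime pairs of 1-Wasserstein distances between the coded
#' emission distributions implied by the configured (low, high) abnormality
#' probabilities. The planted risky set is the argmax set of this spread.
#'
#' @param config A [synth_config()].
#' @return Tibble with `item`, `spread`, and logical `planted`.
#' @export
true_item_spread <- function(config) {
  labs <- which(config$categories == "lab")
  ap <- config$abnormal_prob
  k <- config$n_regimes
  spread <- vapply(seq_along(labs), function(j) {
    dists <- lapply(seq_len(k), function(r) {
      c(ap[r, j, 1], 1 - ap[r, j, 1] - ap[r, j, 2], ap[r, j, 2])
    })
    s <- 0
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      s <- s + wasserstein_1d(c(0, 0.5, 1), dists[[a]], dists[[b]])
    }
    s
  }, numeric(1))
  mx <- max(spread)
  tibble::tibble(
    item = item_names(config$n_items)[labs],
    lab_index = seq_along(labs),
    spread = spread,
    planted = mx > 1e-12 & spread > mx - 1e-12
  )
}

item_names <- function(n_items) {
  cats <- item_categories(n_items)
  nm <- character(n_items)
  nm[cats == "anthropometric"] <- c("height", "weight")[seq_len(sum(cats == "anthropometric"))]
  nm[cats == "gender"] <- "gender"
  nm[cats == "vital"] <- c("temp", "pulse", "bp_max", "bp_min")[seq_len(sum(cats == "vital"))]
  nm[cats == "lab"] <- sprintf("lab%02d", seq_len(sum(cats == "lab")))
  nm
}

#' Generate a synthetic regime-switching EHR cohort
#'
#' Simulates per-patient irregular multivariate time series with the
#' statistical structure the latent-state framework assumes: a discrete
#' clinical regime evolving by a Markov chain, a continuous latent relaxing
#' toward regime anchors by Ornstein-Uhlenbeck (overdamped Langevin) updates,
#' coded lab emissions with regime-dependent abnormality rates, continuous
#' vital/anthropometric readouts of the latent, and death labels tied to
#' absorption in the terminal regime. If `config$missing_rate > 0` the
#' configured missingness mechanism is applied before returning.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_cohort`: list with `sequences` (per patient: `x`
#'   value matrix `T x n_items` with `NA` at missing cells, `x_full` the
#'   complete ground truth, logical `mask`, `regimes`, latent path `z`),
#'   `meta` (patient_id, sex, death_flag, drugs), `items` tibble,
#'   `planted_risky_items`, and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, "generate_cohort"), {
    k <- cfg$n_regimes
    d <- cfg$latent_dim
    anchors <- matrix(rnorm(k * d, sd = cfg$langevin$anchor_scale), k, d)
    labs <- which(cfg$categories == "lab")
    cont <- which(cfg$categories %in% c("anthropometric", "vital"))
    # continuous items read out the latent through fixed random loadings
    loadings <- matrix(rnorm(d * length(cont), sd = 0.5), d, length(cont))
    nm <- item_names(cfg$n_items)

    sequences <- vector("list", cfg$n_patients)
    death <- integer(cfg$n_patients)
    sex <- integer(cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      T_i <- if (cfg$length_range[1] == cfg$length_range[2]) cfg$length_range[1] else
        sample(cfg$length_range[1]:cfg$length_range[2], 1)
      regimes <- integer(T_i)
      regimes[1] <- sample.int(k, 1)
      for (t in seq_len(T_i - 1)) {
        regimes[t + 1] <- sample.int(k, 1, prob = cfg$regime_transition_matrix[regimes[t], ])
      }
      z <- matrix(0, T_i, d)
      z[1, ] <- anchors[regimes[1], ] + rnorm(d, sd = cfg$langevin$noise_scale)
      lv <- cfg$langevin
      for (t in seq_len(T_i - 1)) {
        drift <- lv$drift_strength * (anchors[regimes[t + 1], ] - z[t, ])
        z[t + 1, ] <- z[t, ] + lv$step_size * drift +
          lv$noise_scale * sqrt(lv$step_size) * rnorm(d)
      }
      x <- matrix(NA_real_, T_i, cfg$n_items, dimnames = list(NULL, nm))
      sex[i] <- sample(0:1, 1)
      x[, cfg$categories == "gender"] <- sex[i]
      if (length(cont)) {
        x[, cont] <- z %*% loadings + matrix(rnorm(T_i * length(cont), sd = 0.3),
                                             T_i, length(cont))
      }
      if (length(labs)) {
        low <- cfg$abnormal_prob[regimes, , 1, drop = FALSE]
        high <- cfg$abnormal_prob[regimes, , 2, drop = FALSE]
        dim(low) <- dim(high) <- c(T_i, length(labs))
        u <- matrix(runif(T_i * length(labs)), T_i, length(labs))
        coded <- matrix(0.5, T_i, length(labs))
        coded[u < low] <- 0
        coded[u >= low & u < low + high] <- 1
        if (cfg$emission == "raw") {
          # map codes to raw values around per-item reference ranges
          rr <- synthetic_reference_ranges(length(labs))
          mid <- (rr$lower + rr$upper) / 2
          span <- (rr$upper - rr$lower) / 2
          raw <- coded
          for (j in seq_along(labs)) {
            lo_j <- coded[, j] == 0; hi_j <- coded[, j] == 1; nm_j <- coded[, j] == 0.5
            raw[nm_j, j] <- mid[j] + runif(sum(nm_j), -0.9, 0.9) * span[j]
            raw[lo_j, j] <- rr$lower[j] - runif(sum(lo_j), 0.1, 1) * span[j]
            raw[hi_j, j] <- rr$upper[j] + runif(sum(hi_j), 0.1, 1) * span[j]
          }
          x[, labs] <- raw
        } else {
          x[, labs] <- coded
        }
      }
      death[i] <- as.integer(regimes[T_i] == cfg$death_regime)
      sequences[[i]] <- list(
        patient_id = sprintf("P%05d", i),
        x = x, x_full = x,
        mask = matrix(TRUE, T_i, cfg$n_items, dimnames = list(NULL, nm)),
        regimes = regimes, z = z
      )
    }

    cohort <- structure(list(
      sequences = sequences,
      meta = tibble::tibble(
        patient_id = vapply(sequences, `[[`, "", "patient_id"),
        sex = sex, death_flag = death, drugs = ""
      ),
      items = tibble::tibble(item = nm, category = cfg$categories),
      planted_risky_items = dplyr::filter(true_item_spread(cfg), .data$planted)$item,
      anchors = anchors,
      config = cfg
    ), class = "synthetic_cohort")
  })
  if (cfg$missing_rate > 0) {
    cohort <- apply_missingness(cohort, cfg$missing_mechanism, cfg$missing_rate,
                                mult = cfg$mnar_mult,
                                seed = derive_seed(cfg$seed, "missingness"))
  }
  cohort
}

# Synthetic per-item reference ranges used by the raw emission mode; labelled
# synthetic, not institutional values.
synthetic_reference_ranges <- function(n_labs) {
  lower <- 10 + 2 * seq_len(n_labs)
  tibble::tibble(item = sprintf("lab%02d", seq_len(n_labs)),
                 lower = lower, upper = lower + 6)
}

#' Mask cells of a synthetic cohort missing
#'
#' NCAR masks every (patient, time, item) cell independently with probability
#' `rate`. MNAR masks abnormal coded cells (0 or 1) with probability `mult`
#' times that of normal cells (a cell is abnormal when its value differs
#' from the normal code 0.5), with the base probability solved so the
#' marginal missing fraction equals `rate`. Original values are retained in
#' `x_full` as ground truth for imputation benchmarking.
#'
#' @param cohort A `synthetic_cohort`.
#' @param mechanism `"NCAR"` or `"MNAR"`.
#' @param rate Target marginal missing fraction in `[0, 1)`.
#' @param mult MNAR probability multiplier for abnormal cells (> 1 makes
#'   abnormal values more often missing).
#' @param seed Integer seed.
#' @return The cohort with updated masks and `NA` at masked cells of `x`.
#' @export
apply_missingness <- function(cohort, mechanism = c("NCAR", "MNAR"), rate,
                              mult = 3, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mechanism <- match.arg(mechanism)
  if (!(is.numeric(rate) && length(rate) == 1 && rate >= 0 && rate < 1)) {
    abort("rate must lie in [0, 1)")
  }
  if (rate == 0) return(cohort)

  if (mechanism == "MNAR") {
    # base probability for normal cells so that the marginal equals `rate`
    vals <- unlist(lapply(cohort$sequences, function(s) s$x_full))
    f_ab <- mean(vals != 0.5, na.rm = TRUE)
    p_norm <- rate / (f_ab * mult + (1 - f_ab))
    p_ab <- min(1, mult * p_norm)
    if (p_ab == 1 && abs(f_ab * p_ab + (1 - f_ab) * p_norm - rate) > 0.02) {
      abort("MNAR rate/mult combination infeasible: capped abnormal probability")
    }
  }

  with_seed(derive_seed(seed, paste0("missing_", mechanism)), {
    cohort$sequences <- lapply(cohort$sequences, function(s) {
      u <- matrix(runif(length(s$x_full)), nrow(s$x_full), ncol(s$x_full))
      if (mechanism == "NCAR") {
        drop <- u < rate
      } else {
        p <- matrix(p_norm, nrow(s$x_full), ncol(s$x_full))
        p[s$x_full != 0.5] <- p_ab
        drop <- u < p
      }
      s$mask <- s$mask & !drop
      s$x <- s$x_full
      s$x[!s$mask] <- NA_real_
      s
    })
  })
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  lens <- vapply(x$sequences, function(s) nrow(s$x), integer(1))
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d items, lengths %d-%d, %.1f%% missing, %d deaths\n",
    length(x$sequences), ncol(x$sequences[[1]]$x), min(lens), max(lens),
    100 * mean(vapply(x$sequences, function(s) mean(!s$mask), numeric(1))),
    sum(x$meta$death_flag)))
  invisible(x)
}

#' Long-format observations of a synthetic cohort
#'
#' @param x A `synthetic_cohort`.
#' @param ... Unused.
#' @return Long tibble (patient_id, time_index, item, value) with one row per
#'   observed cell, the same layout the EHR reader consumes.
#' @method as_tibble synthetic_cohort
#' @export
as_tibble.synthetic_cohort <- function(x, ...) {
  purrr::map_dfr(x$sequences, function(s) {
    obs <- which(s$mask, arr.ind = TRUE)
    tibble::tibble(
      patient_id = s$patient_id,
      time_index = obs[, 1],
      item = colnames(s$x)[obs[, 2]],
      value = s$x[obs]
    )
  }) |> dplyr::arrange(.data$patient_id, .data$time_index, .data$item)
}

#' Write a synthetic cohort to delimited text
#'
#' Emits the same long-format observations CSV the real-data reader consumes,
#' a metadata CSV, and a ground-truth JSON sidecar (regime paths, planted
#' items, seed and config echo).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- as_tibble.synthetic_cohort(cohort)
  obs$date <- as.character(as.Date("2006-01-01") + obs$time_index - 1)
  utils::write.csv(obs[, c("patient_id", "date", "item", "value")],
                   file.path(dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (cohort$config$emission == "raw") {
    rr <- synthetic_reference_ranges(sum(cohort$items$category == "lab"))
    utils::write.csv(rr, file.path(dir, "reference_ranges.csv"), row.names = FALSE)
  }
  truth <- list(
    seed = cohort$config$seed,
    planted_risky_items = cohort$planted_risky_items,
    death_regime = cohort$config$death_regime,
    regimes = setNames(lapply(cohort$sequences, `[[`, "regimes"),
                       vapply(cohort$sequences, `[[`, "", "patient_id")),
    config = list(n_patients = cohort$config$n_patients,
                  n_items = cohort$config$n_items,
                  n_regimes = cohort$config$n_regimes,
                  missing_rate = cohort$config$missing_rate,
                  missing_mechanism = cohort$config$missing_mechanism,
                  length_range = cohort$config$length_range)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
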