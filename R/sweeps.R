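#' Log-spaced sigma* grid for one balance sign
#'
#' @param n_points Number of magnitudes (default 16).
#' @param range Magnitude range (default `c(1e-2, 1e3)`, the supported sweep
#'   regime spanning the full balance range).
#' @param sign `+1` or `-1`.
#' @return Numeric vector of signed sigma* values, ordered by magnitude.
#' @examples
#' sigma_star_grid(8, sign = -1)
#' @export
sigma_star_grid <- function(n_points = 16, range = c(1e-2, 1e3), sign = 1) {
  stopifnot(sign %in% c(-1, 1))
  sign * 10^seq(log10(range[1]), log10(range[2]), length.out = n_points)
}

#' Configuration of a parameter sweep over (N, K, sigma*)
#'
#' Bundles the grids and ensemble sizes for [run_dynamics_sweep()] and
#' [run_task_sweep()]. The full-scale study conditions are
#' `n = c(100, 1000, 10000)`, `k` between 1 and 16, 100 reservoirs per grid
#' point for dynamics and 20 for tasks, free runs of 2000 steps with the
#' second half steady; those are the defaults. Scaled-down presets for desk
#' use are available via [sweep_preset()].
#'
#' @param n Reservoir sizes.
#' @param k In-degrees.
#' @param sigma_star Signed sigma* grid (combine signs by concatenation).
#' @param r_dynamics Reservoirs per grid point for dynamics ensembles.
#' @param r_task Reservoirs per grid point and task setting.
#' @param steps Free-run duration.
#' @param t0 Steady-window start (trace steps `> t0` are steady).
#' @param active_fraction Initial active fraction.
#' @param variant BiEntropy variant for steady windows (default
#'   `"logarithmic"`; see [bientropy()]).
#' @param deltas Memory-task difficulty ladder.
#' @param taus Prediction-task Mackey-Glass delays.
#' @param task_length,washout,train_frac Series geometry for tasks.
#' @param train A [train_config()].
#' @param include_zero_balance Add, per (n, k), an exact-zero-balance probe
#'   point (signs assigned to weight magnitudes in equal counts) to the task
#'   sweep; plain sigma*-sampling cannot reach b = 0.
#' @param zero_balance_sigma Magnitude of the weight law used for the b = 0
#'   probe (default 1000, the sweep-regime endpoint where the balance vanishes:
#'   the symmetry dip is a property of the large-|sigma*| regime, where
#'   synaptic magnitudes dwarf the external input).
#' @param base_seed Base seed; every reservoir/replicate stream is derived
#'   from it with [derive_seed()].
#' @param checkpoint_dir If non-`NULL`, per-grid-point results are written
#'   there as CSV and finished points are skipped on re-run, so an
#'   interrupted sweep resumes to the identical table.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(n = c(100, 1000, 10000),
                         k = c(1, 2, 3, 4, 8, 16),
                         sigma_star = c(sigma_star_grid(16, sign = -1),
                                        sigma_star_grid(16, sign = 1)),
                         r_dynamics = 100, r_task = 20,
                         steps = 2000, t0 = 1000, active_fraction = 0.2,
                         variant = "logarithmic",
                         deltas = c(-2, -6, -10, -14, -18),
                         taus = c(5, 15, 28),
                         task_length = 2600, washout = 100, train_frac = 0.8,
                         train = train_config(),
                         include_zero_balance = FALSE,
                         zero_balance_sigma = 1000,
                         base_seed = 1L,
                         checkpoint_dir = NULL) {
  stopifnot(length(n) >= 1, length(k) >= 1, length(sigma_star) >= 1,
            r_dynamics >= 1, r_task >= 1)
  structure(
    list(n = n, k = k, sigma_star = sigma_star,
         r_dynamics = r_dynamics, r_task = r_task,
         steps = steps, t0 = t0, active_fraction = active_fraction,
         variant = variant, deltas = deltas, taus = taus,
         task_length = task_length, washout = washout, train_frac = train_frac,
         train = train, include_zero_balance = include_zero_balance,
         zero_balance_sigma = zero_balance_sigma,
         base_seed = as.integer(base_seed), checkpoint_dir = checkpoint_dir),
    class = "sweep_config"
  )
}

#' Scaled-down sweep presets
#'
#' Named configurations sized for a single desk CPU, each reproducing one
#' qualitative finding of the full-scale study:
#' \describe{
#'   \item{entropy-transition-mini}{`n = 1000`, `k = 16`, negative balance,
#'     16-point sigma* grid, 30 reservoirs: the order-disorder transition
#'     (low BiEntropy near b = -1, high near b = 0, an above-threshold
#'     variance region between).}
#'   \item{k1-order-mini}{`n = 1000`, `k = 1`, both signs, 8 magnitudes,
#'     30 reservoirs: a `k = 1` reservoir never leaves the ordered phase.}
#'   \item{memory-mini}{`n = 1000`, `k = 4`, near-balanced `sigma* = 25`
#'     (b of about 0.03), all five memory delays, 10 reservoirs, shortened
#'     series (900 steps): difficulty ordering and the b = 0 dip.}
#'   \item{best-k-mini}{`n = 1000`, `k` in (1, 2, 3, 4, 8, 16), a coarse
#'     near-balanced grid, hardest memory setting: best-K summary material.}
#' }
#'
#' @param name Preset name.
#' @param base_seed Base seed.
#' @return A `sweep_config`.
#' @export
sweep_preset <- function(name = c("entropy-transition-mini", "k1-order-mini",
                                  "memory-mini", "best-k-mini"),
                         base_seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "entropy-transition-mini" = sweep_config(
      n = 1000, k = 16, sigma_star = sigma_star_grid(16, sign = -1),
      r_dynamics = 30, base_seed = base_seed
    ),
    "k1-order-mini" = sweep_config(
      n = 1000, k = 1,
      sigma_star = c(sigma_star_grid(8, sign = -1), sigma_star_grid(8, sign = 1)),
      r_dynamics = 30, base_seed = base_seed
    ),
    "memory-mini" = sweep_config(
      n = 1000, k = 4, sigma_star = 25,
      r_task = 10, deltas = c(-2, -6, -10, -14, -18), taus = numeric(),
      task_length = 900, washout = 50,
      include_zero_balance = TRUE, zero_balance_sigma = 1000,
      base_seed = base_seed
    ),
    "best-k-mini" = sweep_config(
      n = 1000, k = c(1, 2, 3, 4, 8, 16),
      sigma_star = sigma_star_from_balance(c(0.02, 0.05, 0.1, 0.3)),
      r_task = 10, deltas = -18, taus = numeric(),
      task_length = 900, washout = 50, base_seed = base_seed
    )
  )
}

grid_points <- function(cfg) {
  tidyr::expand_grid(n = cfg$n, k = cfg$k, sigma_star = cfg$sigma_star) |>
    dplyr::filter(.data$k <= .data$n - 1) |>
    dplyr::mutate(b = balance_from_sigma_star(.data$sigma_star))
}

checkpoint_path <- function(dir, kind, n, k, sigma_star, extra = NULL) {
  file.path(dir, paste0(
    kind, "_n", n, "_k", k, "_s", sprintf("%.6g", sigma_star),
    if (!is.null(extra)) paste0("_", extra), ".csv"
  ))
}

#' Free-running dynamics sweep: per-run BiEntropy and attractor label
#'
#' For every grid point (n, k, sigma*) of the configuration, generates
#' `r_dynamics` seeded reservoirs, runs each freely for `steps` updates,
#' computes the BiEntropy of the binarized steady activity and classifies the
#' steady attractor. Deterministic in `base_seed`; resumable through
#' `checkpoint_dir`.
#'
#' @param cfg A [sweep_config()].
#' @param .progress Print one line per grid point (default `FALSE`).
#' @return A tibble of per-run rows (`n`, `k`, `sigma_star`, `b`, `replicate`,
#'   `seed`, `hb`, `category`, `period`) with class `rbn_dynamics_runs`;
#'   aggregate with [summarize_dynamics()].
#' @export
run_dynamics_sweep <- function(cfg, .progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  grid <- grid_points(cfg)
  rows <- purrr::pmap(grid, function(n, k, sigma_star, b) {
    ckpt <- if (!is.null(cfg$checkpoint_dir)) {
      checkpoint_path(cfg$checkpoint_dir, "dynamics", n, k, sigma_star)
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      return(readr::read_csv(ckpt, col_types = "iiddiidci", progress = FALSE))
    }
    if (.progress) {
      message(sprintf("dynamics: n = %d, k = %d, sigma* = %.4g", n, k, sigma_star))
    }
    point <- purrr::map_dfr(seq_len(cfg$r_dynamics), function(r) {
      seed <- derive_seed(cfg$base_seed, "dynamics", n, k, sprintf("%.10g", sigma_star), r)
      res <- build_reservoir(reservoir_spec(n, k, sigma_star, seed = seed))
      run <- free_run(res, steps = cfg$steps,
                      active_fraction = cfg$active_fraction,
                      seed = derive_seed(seed, "init"))
      steady <- as.numeric(run$trace)[(cfg$t0 + 1):cfg$steps]
      label <- classify_attractor(steady, n = n)
      tibble::tibble(
        n = n, k = k, sigma_star = sigma_star, b = b,
        replicate = r, seed = seed,
        hb = bientropy(as.integer(steady > mean(steady)), variant = cfg$variant),
        category = as.character(label$category), period = label$period
      )
    })
    if (!is.null(ckpt)) {
      dir.create(dirname(ckpt), recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(point, ckpt)
    }
    point
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rbn_dynamics_runs", class(out))
  out
}

#' Aggregate a dynamics sweep into per-grid-point ensemble statistics
#'
#' @param runs Output of [run_dynamics_sweep()].
#' @return A tibble with one row per (n, k, sigma*): ensemble mean and
#'   population variance of BiEntropy, attractor-category percentages, and the
#'   ensemble size; class `rbn_dynamics_summary`.
#' @export
summarize_dynamics <- function(runs) {
  out <- runs |>
    dplyr::group_by(.data$n, .data$k, .data$sigma_star, .data$b) |>
    dplyr::summarise(
      mean_hb = mean(.data$hb),
      var_hb = mean((.data$hb - mean(.data$hb))^2),
      pct_extinguished = 100 * mean(.data$category == "extinguished"),
      pct_fixed = 100 * mean(.data$category == "fixed"),
      pct_cyclic = 100 * mean(.data$category == "cyclic"),
      pct_irregular = 100 * mean(.data$category == "irregular"),
      r = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$n, .data$k, abs(.data$sigma_star))
  class(out) <- c("rbn_dynamics_summary", class(out))
  out
}

#' Task-performance sweep: one record per reservoir and task setting
#'
#' For every grid point and every task setting (memory delays `deltas`,
#' prediction `taus`), generates `r_task` seeded reservoirs, runs the full
#' drive/train/score protocol ([run_task_on_reservoir()]) and returns the raw
#' performance records. When `include_zero_balance` is set, an exact-b = 0
#' probe point is added per (n, k). Deterministic in `base_seed`; resumable
#' through `checkpoint_dir`.
#'
#' @param cfg A [sweep_config()].
#' @param .progress Print one line per grid point and task (default `FALSE`).
#' @return A tibble of performance records with class `rbn_performance_runs`;
#'   aggregate with [summarize_performance()].
#' @export
run_task_sweep <- function(cfg, .progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  tasks <- dplyr::bind_rows(
    if (length(cfg$deltas) > 0) tibble::tibble(task = "memory", difficulty = as.numeric(cfg$deltas)),
    if (length(cfg$taus) > 0) tibble::tibble(task = "prediction", difficulty = as.numeric(cfg$taus))
  )
  if (nrow(tasks) == 0) {
    out <- tibble::tibble(
      n = integer(), k = integer(), sigma_star = numeric(), b = numeric(),
      task = character(), difficulty = numeric(), seed = integer(),
      correlation = numeric(), final_loss = numeric(), degenerate = logical(),
      replicate = integer()
    )
    class(out) <- c("rbn_performance_runs", class(out))
    return(out)
  }
  grid <- grid_points(cfg)
  if (isTRUE(cfg$include_zero_balance)) {
    zero <- tidyr::expand_grid(n = cfg$n, k = cfg$k) |>
      dplyr::filter(.data$k <= .data$n - 1) |>
      dplyr::mutate(sigma_star = cfg$zero_balance_sigma, b = 0)
    grid <- dplyr::bind_rows(
      dplyr::mutate(grid, exact_zero = FALSE),
      dplyr::mutate(zero, exact_zero = TRUE)
    )
  } else {
    grid$exact_zero <- FALSE
  }
  cells <- tidyr::expand_grid(grid, tasks)
  rows <- purrr::pmap(cells, function(n, k, sigma_star, b, exact_zero, task, difficulty) {
    tag <- paste0(task, difficulty, if (exact_zero) "_b0" else "")
    ckpt <- if (!is.null(cfg$checkpoint_dir)) {
      checkpoint_path(cfg$checkpoint_dir, "task", n, k, sigma_star, tag)
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      return(readr::read_csv(ckpt, col_types = "iiddcdiddli", progress = FALSE))
    }
    if (.progress) {
      message(sprintf("task %s (%g): n = %d, k = %d, sigma* = %.4g%s",
                      task, difficulty, n, k, sigma_star,
                      if (exact_zero) " [b = 0]" else ""))
    }
    point <- purrr::map_dfr(seq_len(cfg$r_task), function(r) {
      seed <- derive_seed(cfg$base_seed, "task", n, k, sprintf("%.10g", sigma_star),
                          tag, r)
      res <- build_reservoir(reservoir_spec(
        n, k, sigma_star, seed = seed, exact_zero_balance = exact_zero
      ))
      task_obj <- if (task == "memory") {
        make_memory_task(difficulty, length = cfg$task_length,
                         washout = cfg$washout, train_frac = cfg$train_frac,
                         seed = derive_seed(seed, "noise"))
      } else {
        make_prediction_task(difficulty, length = cfg$task_length,
                             washout = cfg$washout, train_frac = cfg$train_frac)
      }
      cfg_train <- cfg$train
      cfg_train$seed <- derive_seed(seed, "readout-init")
      rec <- run_task_on_reservoir(res, task_obj, cfg_train,
                                   state_seed = derive_seed(seed, "init"))
      rec$replicate <- r
      rec
    })
    if (!is.null(ckpt)) {
      dir.create(dirname(ckpt), recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(point, ckpt)
    }
    point
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rbn_performance_runs", class(out))
  out
}

#' Aggregate task records into per-grid-point mean and standard deviation
#'
#' @param records Output of [run_task_sweep()] (raw performance records).
#' @return A tibble with one row per (n, k, sigma*, b, task, difficulty):
#'   `mean_corr`, `sd_corr`, `r`; class `rbn_performance_summary`.
#' @export
summarize_performance <- function(records) {
  out <- records |>
    dplyr::group_by(.data$n, .data$k, .data$sigma_star, .data$b,
                    .data$task, .data$difficulty) |>
    dplyr::summarise(
      mean_corr = mean(.data$correlation),
      sd_corr = sd(.data$correlation),
      r = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("rbn_performance_summary", class(out))
  out
}

hardest_setting <- function(task) {
  switch(task, memory = -18, prediction = 28,
         abort(sprintf("unknown task '%s'.", task), class = "rbn_domain_error"))
}

#' Balance maximizing mean performance at the hardest task setting
#'
#' Selects, among the grid points of one (n, k, sign), the balance whose mean
#' correlation at the hardest setting (delay -18 for memory, tau 28 for
#' prediction) is largest; ties break toward smaller `|b|`. This is the
#' balance at which performance curves and best-K summaries are reported.
#'
#' @param summary An `rbn_performance_summary` (see [summarize_performance()]).
#' @param n,k Grid point.
#' @param sign Balance sign to search (+1 or -1).
#' @param task `"memory"` or `"prediction"`.
#' @return One-row tibble: `n`, `k`, `sign`, `task`, `b_opt`,
#'   `sigma_star_opt`, `mean_corr`.
#' @export
select_b_opt <- function(summary, n, k, sign, task) {
  hardest <- hardest_setting(task)
  cand <- summary |>
    dplyr::filter(.data$n == !!n, .data$k == !!k, .data$task == !!task,
                  .data$difficulty == hardest, sign(.data$b) == !!sign)
  if (nrow(cand) == 0) {
    abort(sprintf(
      "no rows at the hardest setting (%s %g) for n = %s, k = %s, sign %s.",
      task, hardest, n, k, sign
    ), class = "rbn_coverage_error")
  }
  best <- cand |>
    dplyr::arrange(dplyr::desc(.data$mean_corr), abs(.data$b)) |>
    dplyr::slice(1)
  tibble::tibble(
    n = best$n, k = best$k, sign = sign, task = task,
    b_opt = best$b, sigma_star_opt = best$sigma_star, mean_corr = best$mean_corr
  )
}

#' Best performance per in-degree at the optimal balance
#'
#' For each (k, sign, task) present in the table, finds the optimal balance
#' with [select_b_opt()] and reports the mean and standard deviation of the
#' correlation at that balance for every difficulty — the per-K summary of
#' where reservoir design pays off.
#'
#' @param summary An `rbn_performance_summary`.
#' @return A tibble with one row per (n, k, sign, task, difficulty) at b_opt;
#'   class `rbn_best_k`.
#' @export
summarize_best_k <- function(summary) {
  keys <- summary |>
    dplyr::mutate(sign = sign(.data$b)) |>
    dplyr::filter(.data$sign != 0) |>
    dplyr::distinct(.data$n, .data$k, .data$sign, .data$task)
  out <- purrr::pmap_dfr(keys, function(n, k, sign, task) {
    opt <- select_b_opt(summary, n, k, sign, task)
    summary |>
      dplyr::filter(.data$n == !!n, .data$k == !!k, .data$task == !!task,
                    .data$b == opt$b_opt) |>
      dplyr::mutate(sign = !!sign, b_opt = opt$b_opt) |>
      dplyr::select("n", "k", "sign", "task", "difficulty", "b_opt",
                    "sigma_star", "mean_corr", "sd_corr", "r")
  })
  class(out) <- c("rbn_best_k", class(out))
  out
}
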