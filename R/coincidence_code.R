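# The discrimination experiment: binary activation vectors, contactable
# pools, rotation sweeps with the 5% Hamming criterion, and the paired
# subfield-vs-uniform population experiment.

#' Population activation vector for an edge stimulus
#'
#' One bit per unit: active iff the edge segment passes within the radius of
#' any of the unit's receptor elements (strict inequality).
#'
#' @param pop a `fingertip_model`.
#' @param edge an [edge_stimulus()].
#' @param rotate_by extra rotation (degrees) of the edge about its center.
#' @return logical vector indexed by unit id.
#' @export
activation_vector <- function(pop, edge, rotate_by = 0) {
  act <- element_active(pop$elements, edge, rotate_by)
  tabulate(pop$elements$unit_id[act], nbins = nrow(pop$units)) > 0L
}

#' Contactable pool of an edge rotating about a point
#'
#' The number of units that could be contacted if the edge rotated completely
#' about its center (N_c), the normalization factor of the 5% discrimination
#' criterion.  Computed analytically: a full rotation of a centered segment of
#' half-length h sweeps every direction from the center, so an element is
#' reachable iff `distance(element center, rotation center) < h + element
#' radius` (strict, matching the activation rule).  `method = "sweep"` instead
#' unions activation over a dense grid of orientations and serves as an
#' independent cross-check of the analytic rule.
#'
#' @param pop a `fingertip_model`.
#' @param center rotation center (mm), default the patch center.
#' @param length edge length (mm; `Inf` for the 44 mm edge).
#' @param method `"analytic"` (default) or `"sweep"`.
#' @param sweep_step orientation grid step (degrees) for `method = "sweep"`.
#' @return list with `n` (pool size) and `unit_ids`.
#' @export
contactable_pool <- function(pop, center = patch_center(pop), length,
                             method = c("analytic", "sweep"),
                             sweep_step = 0.1) {
  method <- match.arg(method)
  h <- if (is.infinite(length)) INFINITE_EDGE_MM / 2 else length / 2
  el <- pop$elements
  if (method == "analytic") {
    reach <- sqrt((el$x - center[1])^2 + (el$y - center[2])^2) < h + el$radius
    ids <- sort(unique(el$unit_id[reach]))
  } else {
    edge <- edge_stimulus(center, length, 0)
    # only elements within reach can ever activate; restrict for speed
    near <- sqrt((el$x - center[1])^2 + (el$y - center[2])^2) <
      h + el$radius + 1e-9
    eln <- el[near, ]
    hit <- rep(FALSE, nrow(eln))
    for (th in seq(0, 180 - sweep_step, by = sweep_step)) {
      hit <- hit | element_active(eln, edge, rotate_by = th)
      if (all(hit)) break
    }
    ids <- sort(unique(eln$unit_id[hit]))
  }
  list(n = length(ids), unit_ids = ids)
}

#' Edge-orientation discrimination threshold of a population
#'
#' Rotates the edge about its center in fixed increments and returns the
#' smallest rotation at which the Hamming distance between the initial
#' activation vector and the rotated one reaches `criterion * N_c`, where
#' N_c is the contactable pool size.  Units outside the pool can never change
#' state, so the Hamming distance is computed over pool units only.
#'
#' A rotation of 180 degrees maps a segment onto itself, so the search stops
#' there; stimuli whose activation never changes by the criterion (e.g. the
#' raised dot, which is rotation-invariant) yield `threshold = NA`, reported
#' as such rather than coerced to any angle.
#'
#' @param pop a `fingertip_model`.
#' @param edge an [edge_stimulus()] (typically centered on the patch).
#' @param step rotation increment (degrees).
#' @param criterion fraction of the contactable pool that must change state.
#' @param max_angle largest rotation searched (degrees).
#' @return An object of class `threshold_result`: list with `threshold`
#'   (degrees or `NA`), `pool_size`, and `hamming_profile` (Hamming distance
#'   at 0, step, 2*step, ... up to the threshold or `max_angle`).
#' @export
discrimination_threshold <- function(pop, edge, step = 0.5, criterion = 0.05,
                                     max_angle = 180) {
  stopifnot(inherits(pop, "fingertip_model"), inherits(edge, "edge_stimulus"),
            step > 0, criterion > 0)
  pool <- contactable_pool(pop, center = edge$center, length = edge$length)
  if (pool$n < 1L) {
    return(structure(list(threshold = NA_real_, pool_size = 0L,
                          hamming_profile = numeric(0)),
                     class = "threshold_result"))
  }
  h <- edge$length_mm / 2
  el <- pop$elements
  reach <- sqrt((el$x - edge$center[1])^2 + (el$y - edge$center[2])^2) <
    h + el$radius
  el <- el[reach, , drop = FALSE]
  # relabel pool unit ids to 1..n for tabulate()
  uidx <- match(el$unit_id, pool$unit_ids)
  npool <- pool$n
  act0 <- tabulate(uidx[element_active(el, edge, 0)], nbins = npool) > 0L
  ks <- seq_len(floor(max_angle / step))
  profile <- numeric(length(ks) + 1L)  # profile[1] = Hamming at 0 deg = 0
  threshold <- NA_real_
  for (k in ks) {
    act <- tabulate(uidx[element_active(el, edge, k * step)], nbins = npool) > 0L
    ham <- sum(act != act0)
    profile[k + 1L] <- ham
    if (ham >= criterion * npool) {
      threshold <- k * step
      profile <- profile[seq_len(k + 1L)]
      break
    }
  }
  structure(list(threshold = threshold, pool_size = npool,
                 hamming_profile = profile),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "none (criterion never reached)" else
    sprintf("%.1f deg", x$threshold)
  cat(sprintf("<threshold_result> threshold %s, contactable pool %d units\n",
              thr, x$pool_size))
  invisible(x)
}

#' Paired subfield-vs-uniform discrimination experiment
#'
#' For each repetition a subfield fingertip and its uniform twin are built
#' from the same child seed, so that receptive-field sizes, locations and the
#' stimulus placement are identical for both model variants; the same centered
#' edge is applied to both and the discrimination threshold recorded.  Mean
#' thresholds and normal-approximation 95% confidence intervals
#' (mean +/- 1.96 SD/sqrt(n)) are reported per variant and edge length, with
#' undiscriminable (`NA`) outcomes excluded from the averages and counted
#' separately.
#'
#' @param lengths edge lengths (mm); `Inf` denotes the 44 mm edge.
#' @param repetitions number of paired virtual fingertips per length.
#' @param seed root seed; per-fingertip child seeds are derived from it.
#' @param step,criterion rotation increment and Hamming criterion, as in
#'   [discrimination_threshold()].
#' @param config a [fingertip_config()].
#' @return An object of class `experiment_result`: list with `thresholds`
#'   (tibble: `variant`, `length`, `rep`, `seed`, `threshold`, `pool_size`),
#'   `summary` (tibble: `variant`, `length`, `n`, `n_none`, `mean`, `sd`,
#'   `ci_low`, `ci_high`) and `paired_diff` (tibble of mean uniform-minus-
#'   subfield differences per length).
#' @export
run_paired_experiment <- function(lengths = c(1, 2, 4, 8, Inf),
                                  repetitions = 100, seed = 1,
                                  step = 0.5, criterion = 0.05,
                                  config = fingertip_config()) {
  stopifnot(length(lengths) >= 1, repetitions >= 1)
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  rows <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    sub <- build_fingertip(child_seeds[r], "subfield", config)
    uni <- make_uniform_twin(sub)
    ctr <- patch_center(sub)
    res <- lapply(lengths, function(L) {
      edge <- edge_stimulus(ctr, L, 0)
      ts <- discrimination_threshold(sub, edge, step, criterion)
      tu <- discrimination_threshold(uni, edge, step, criterion)
      tibble::tibble(
        variant = c("subfield", "uniform"),
        length = L,
        rep = r,
        seed = child_seeds[r],
        threshold = c(ts$threshold, tu$threshold),
        pool_size = c(ts$pool_size, tu$pool_size)
      )
    })
    rows[[r]] <- dplyr::bind_rows(res)
  }
  thresholds <- dplyr::bind_rows(rows)
  summary <- thresholds |>
    dplyr::group_by(.data$variant, .data$length) |>
    dplyr::summarise(
      n = sum(!is.na(.data$threshold)),
      n_none = sum(is.na(.data$threshold)),
      mean = mean(.data$threshold, na.rm = TRUE),
      sd = sd(.data$threshold, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = .data$mean - 1.96 * .data$sd / sqrt(.data$n),
      ci_high = .data$mean + 1.96 * .data$sd / sqrt(.data$n)
    )
  bad <- summary$n_none > repetitions / 2
  if (any(bad)) {
    stop("run_paired_experiment: more than half the repetitions yielded no ",
         "threshold for length(s) ",
         paste(unique(summary$length[bad]), collapse = ", "),
         "; result not summarizable")
  }
  paired_diff <- thresholds |>
    dplyr::group_by(.data$length, .data$rep) |>
    dplyr::summarise(
      diff = .data$threshold[.data$variant == "uniform"] -
        .data$threshold[.data$variant == "subfield"],
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      n = sum(!is.na(.data$diff)),
      mean_diff = mean(.data$diff, na.rm = TRUE),
      sd_diff = sd(.data$diff, na.rm = TRUE),
      .groups = "drop"
    )
  structure(list(thresholds = thresholds, summary = summary,
                 paired_diff = paired_diff,
                 lengths = lengths, repetitions = repetitions, seed = seed,
                 step = step, criterion = criterion, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d paired fingertips, lengths: %s\n",
              x$repetitions, paste(x$lengths, collapse = ", ")))
  print(as.data.frame(x$summary), digits = 3)
  cat("paired uniform - subfield differences:\n")
  print(as.data.frame(x$paired_diff), digits = 3)
  invisible(x)
}

#' Tidy per-repetition thresholds of an experiment
#'
#' @param result an `experiment_result`.
#' @return tibble (`variant`, `length`, `rep`, `seed`, `threshold`,
#'   `pool_size`).
#' @export
experiment_thresholds <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  result$thresholds
}
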