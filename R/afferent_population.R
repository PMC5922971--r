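# Construction of virtual fingertips: unit placement at the human innervation
# spacing, receptive-field size sampling, and receptor-element layouts for the
# subfield and uniform model variants.

SUBFIELD_ELEMENT_RADIUS <- 0.125  # mm; 250 micron diameter transduction sites

#' Default fingertip model configuration
#'
#' Parameters of the virtual skin patch and its afferent population.
#'
#' * `patch_width`, `patch_height`: patch size in mm (default 20 x 20, i.e.
#'   a 2 x 2 cm patch).
#' * `target_spacing`, `spacing_tolerance`: units are added until the mean
#'   distance from each unit's receptive-field center to its six nearest
#'   neighbours first falls to `target_spacing + spacing_tolerance` (mm).
#' * `rf_size_interpretation`: whether the log-normal receptive-field size
#'   distribution (log10 mean 1, SD 0.45) describes RF *area* in mm^2
#'   (default; median area 10 mm^2, diameter ~3.6 mm) or RF *diameter* in mm.
#' * `element_count_range`: inclusive range of the discrete-uniform number of
#'   receptor elements per subfield-variant unit.
#' * `element_radius`: subfield receptor-element radius (mm).
#'
#' @param patch_width,patch_height patch dimensions (mm).
#' @param target_spacing target mean 6-nearest-neighbour spacing (mm).
#' @param spacing_tolerance placement stopping tolerance (mm).
#' @param rf_log10_mean,rf_log10_sd log10-scale parameters of the RF size
#'   distribution.
#' @param rf_size_interpretation `"area"` or `"diameter"`.
#' @param element_count_range length-2 integer vector.
#' @param element_radius subfield element radius (mm).
#' @param max_units safety cap on the number of placed units.
#' @return A list of class `fingertip_config`.
#' @export
fingertip_config <- function(patch_width = 20, patch_height = 20,
                             target_spacing = 1.0, spacing_tolerance = 0.02,
                             rf_log10_mean = 1, rf_log10_sd = 0.45,
                             rf_size_interpretation = c("area", "diameter"),
                             element_count_range = c(2L, 64L),
                             element_radius = SUBFIELD_ELEMENT_RADIUS,
                             max_units = 5000L) {
  rf_size_interpretation <- match.arg(rf_size_interpretation)
  stopifnot(patch_width > 0, patch_height > 0, target_spacing > 0,
            spacing_tolerance > 0, rf_log10_sd >= 0,
            length(element_count_range) == 2L,
            element_count_range[1] >= 2L,
            element_count_range[1] <= element_count_range[2],
            element_radius > 0, max_units > 7L)
  structure(
    list(patch_width = patch_width, patch_height = patch_height,
         target_spacing = target_spacing, spacing_tolerance = spacing_tolerance,
         rf_log10_mean = rf_log10_mean, rf_log10_sd = rf_log10_sd,
         rf_size_interpretation = rf_size_interpretation,
         element_count_range = as.integer(element_count_range),
         element_radius = element_radius, max_units = as.integer(max_units)),
    class = "fingertip_config"
  )
}

#' Sample receptive-field radii
#'
#' Receptive-field sizes follow a log-normal distribution with log10-scale
#' mean 1 and SD 0.45, per human microneurography.  Under the default "area"
#' interpretation the sampled quantity `10^x` is the RF area in mm^2 and the
#' radius is `sqrt(area / pi)` (median area 10 mm^2, radius 1.784 mm).  Under
#' the "diameter" interpretation `10^x` is the RF diameter in mm.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param n number of radii to draw.
#' @param config a [fingertip_config()].
#' @return numeric vector of radii (mm).
#' @export
sample_rf_radius <- function(n, config = fingertip_config()) {
  x <- rnorm(n, config$rf_log10_mean, config$rf_log10_sd)
  switch(config$rf_size_interpretation,
         area = sqrt(10^x / pi),
         diameter = 10^x / 2)
}

#' Place unit centers at the target innervation spacing
#'
#' Receptive-field centers are drawn uniformly at random on the patch and
#' accumulated one at a time; placement stops at the first count at which the
#' mean distance from each center to its six nearest neighbours falls to
#' `target_spacing + spacing_tolerance`.  The 6-NN statistic is maintained
#' incrementally so placement is O(n^2) overall.
#'
#' @param config a [fingertip_config()].
#' @return numeric matrix with columns `x`, `y` (mm).
#' @export
place_unit_centers <- function(config = fingertip_config()) {
  w <- config$patch_width; h <- config$patch_height
  target <- config$target_spacing + config$spacing_tolerance
  nmax <- config$max_units
  xs <- runif(nmax, 0, w)
  ys <- runif(nmax, 0, h)
  # knn[i, ] holds the 6 smallest distances from point i to the others, sorted
  knn <- matrix(Inf, nrow = nmax, ncol = 6L)
  n <- 7L
  d0 <- as.matrix(stats::dist(cbind(xs[1:7], ys[1:7])))
  for (i in 1:7) knn[i, ] <- sort(d0[i, -i])
  repeat {
    if (mean(knn[1:n, ]) <= target) break
    if (n >= nmax) {
      stop("place_unit_centers: spacing criterion not met within max_units (",
           nmax, "); mean 6-NN distance is ", signif(mean(knn[1:n, ]), 4), " mm")
    }
    n <- n + 1L
    d <- sqrt((xs[1:(n - 1)] - xs[n])^2 + (ys[1:(n - 1)] - ys[n])^2)
    upd <- which(d < knn[1:(n - 1), 6L])
    for (i in upd) {
      row <- c(knn[i, ], d[i])
      knn[i, ] <- sort(row)[1:6]
    }
    knn[n, ] <- sort(d)[1:6]
  }
  cbind(x = xs[1:n], y = ys[1:n])
}

#' Mean six-nearest-neighbour distance of a point set
#'
#' Brute-force reference statistic used by the placement stopping rule: for
#' each point, the mean distance to its six nearest neighbours, averaged over
#' points.
#'
#' @param centers numeric matrix with columns `x`, `y`.
#' @return mean 6-NN distance (mm).
#' @export
mean_knn6_distance <- function(centers) {
  n <- nrow(centers)
  if (n < 7L) stop("mean_knn6_distance: at least 7 points required")
  d <- as.matrix(stats::dist(centers))
  mean(vapply(seq_len(n), function(i) mean(sort(d[i, -i])[1:6]), numeric(1)))
}

#' Attach subfield receptor elements to units
#'
#' Each subfield-variant unit receives `n ~ uniform{2..64}` circular receptor
#' elements of 250 micron diameter.  The first two are placed at antipodal
#' points of the receptive-field boundary (a random diameter direction); the
#' remaining `n - 2` centers are uniform on the RF disk.  Elements may overlap.
#'
#' @param units tibble with columns `id`, `x`, `y`, `rf_radius`.
#' @param config a [fingertip_config()].
#' @return tibble of elements with columns `unit_id`, `x`, `y`, `radius`.
#' @export
attach_subfields <- function(units, config = fingertip_config()) {
  rng <- config$element_count_range
  counts <- sample(rng[1]:rng[2], nrow(units), replace = TRUE)
  total <- sum(counts)
  uid <- rep(units$id, counts)
  cx <- rep(units$x, counts)
  cy <- rep(units$y, counts)
  rr <- rep(units$rf_radius, counts)
  # index of each element within its unit (1..n_k)
  within <- sequence(counts)
  ex <- numeric(total); ey <- numeric(total)
  first <- within == 1L
  second <- within == 2L
  phi <- runif(sum(first), 0, 2 * pi)
  phi_all <- rep(phi, counts)  # same diameter direction for elements 1 and 2
  onb <- first | second
  sgn <- ifelse(within[onb] == 1L, 1, -1)
  ex[onb] <- cx[onb] + sgn * rr[onb] * cos(phi_all[onb])
  ey[onb] <- cy[onb] + sgn * rr[onb] * sin(phi_all[onb])
  inner <- !onb
  m <- sum(inner)
  rad <- rr[inner] * sqrt(runif(m))
  ang <- runif(m, 0, 2 * pi)
  ex[inner] <- cx[inner] + rad * cos(ang)
  ey[inner] <- cy[inner] + rad * sin(ang)
  tibble::tibble(unit_id = uid, x = ex, y = ey,
                 radius = config$element_radius)
}

#' Build a virtual fingertip
#'
#' Constructs a population of afferent units on the skin patch: centers placed
#' at the target innervation spacing, receptive-field radii sampled from the
#' log-normal size distribution, and receptor elements attached according to
#' the model variant.  In the `subfield` variant each unit carries 2-64 small
#' receptor elements; in the `uniform` variant each unit carries exactly one
#' element whose size and location coincide with its receptive-field boundary.
#'
#' @param seed integer seed; the construction is fully reproducible given the
#'   seed and config.
#' @param variant `"subfield"` or `"uniform"`.
#' @param config a [fingertip_config()].
#' @return An object of class `fingertip_model`: a list with `units` (tibble:
#'   `id`, `x`, `y`, `rf_radius`), `elements` (tibble: `unit_id`, `x`, `y`,
#'   `radius`), `variant`, `config`, `seed`.
#' @export
#' @examples
#' fp <- build_fingertip(seed = 1)
#' nrow(fp$units)
build_fingertip <- function(seed, variant = c("subfield", "uniform"),
                            config = fingertip_config()) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  centers <- place_unit_centers(config)
  n <- nrow(centers)
  units <- tibble::tibble(
    id = seq_len(n),
    x = centers[, "x"],
    y = centers[, "y"],
    rf_radius = sample_rf_radius(n, config)
  )
  elements <- attach_subfields(units, config)
  pop <- structure(
    list(units = units, elements = elements, variant = "subfield",
         config = config, seed = as.integer(seed)),
    class = "fingertip_model"
  )
  if (variant == "uniform") make_uniform_twin(pop) else pop
}

#' Uniform-receptive-field twin of a subfield fingertip
#'
#' Returns a population with per-unit receptive-field geometry identical to
#' the source (same centers and radii, unit for unit) but with exactly one
#' receptor element per unit, centered on the RF center with radius equal to
#' the RF radius.  Paired subfield/uniform runs use this so that only the
#' receptor-element layout differs between model variants.
#'
#' @param pop a subfield-variant `fingertip_model`.
#' @return a uniform-variant `fingertip_model`.
#' @export
make_uniform_twin <- function(pop) {
  stopifnot(inherits(pop, "fingertip_model"))
  if (pop$variant != "subfield")
    stop("make_uniform_twin: population is already uniform-variant")
  elements <- tibble::tibble(
    unit_id = pop$units$id,
    x = pop$units$x,
    y = pop$units$y,
    radius = pop$units$rf_radius
  )
  structure(
    list(units = pop$units, elements = elements, variant = "uniform",
         config = pop$config, seed = pop$seed),
    class = "fingertip_model"
  )
}

#' Extract one unit with its elements
#'
#' @param pop a `fingertip_model`.
#' @param id unit id.
#' @return list with fields `id`, `rf_center`, `rf_radius`, `elements`.
#' @export
get_unit <- function(pop, id) {
  stopifnot(inherits(pop, "fingertip_model"))
  u <- pop$units[pop$units$id == id, ]
  if (nrow(u) != 1L) stop("get_unit: no unit with id ", id)
  list(id = u$id, rf_center = c(u$x, u$y), rf_radius = u$rf_radius,
       elements = pop$elements[pop$elements$unit_id == id, ])
}

#' @export
print.fingertip_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<fingertip_model> %s variant, %d units, %d elements\n",
    "  patch %g x %g mm, seed %d, mean 6-NN spacing %.3f mm\n"),
    x$variant, nrow(x$units), nrow(x$elements),
    x$config$patch_width, x$config$patch_height, x$seed,
    mean_knn6_distance(as.matrix(x$units[, c("x", "y")]))))
  invisible(x)
}

#' Patch center of a fingertip model
#' @param pop a `fingertip_model`.
#' @return numeric length-2 (mm).
#' @export
patch_center <- function(pop) {
  c(pop$config$patch_width / 2, pop$config$patch_height / 2)
}

#' Serialize a fingertip model to JSON
#'
#' Writes the config header plus flat unit and element tables; the model can
#' be read back with [read_fingertip()] and round-trips exactly (up to double
#' precision in the JSON text).
#'
#' @param pop a `fingertip_model`.
#' @param path output file path (.json).
#' @return `path`, invisibly.
#' @export
write_fingertip <- function(pop, path) {
  stopifnot(inherits(pop, "fingertip_model"))
  obj <- list(
    config = unclass(pop$config),
    variant = pop$variant,
    seed = pop$seed,
    units = as.data.frame(pop$units),
    elements = as.data.frame(pop$elements)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fingertip model from JSON
#'
#' @param path file written by [write_fingertip()].
#' @return a `fingertip_model`.
#' @export
read_fingertip <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- fingertip_config(
    patch_width = cfg$patch_width, patch_height = cfg$patch_height,
    target_spacing = cfg$target_spacing,
    spacing_tolerance = cfg$spacing_tolerance,
    rf_log10_mean = cfg$rf_log10_mean, rf_log10_sd = cfg$rf_log10_sd,
    rf_size_interpretation = cfg$rf_size_interpretation,
    element_count_range = cfg$element_count_range,
    element_radius = cfg$element_radius, max_units = cfg$max_units
  )
  structure(
    list(units = tibble::as_tibble(obj$units),
         elements = tibble::as_tibble(obj$elements),
         variant = obj$variant, config = config, seed = obj$seed),
    class = "fingertip_model"
  )
}
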