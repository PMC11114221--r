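#' Conductance region scheme
#'
#' Partition of the conductance axis into `n_regions` contiguous regions
#' shared by all channels, defined by `n_regions - 1` strictly increasing
#' interior boundaries within `range`. Bins are half-open `[low, high)` with
#' the final bin closed; values tied with a boundary go to the upper region.
#'
#' @param boundaries strictly increasing interior thresholds (uS).
#' @param range length-2 numeric `(low, high)` enclosing all boundaries.
#' @return An object of class `region_scheme`.
#' @seealso [make_region_scheme()], [refine_pattern()]
#' @export
region_scheme <- function(boundaries, range) {
  stopifnot(is.numeric(boundaries), is.numeric(range), length(range) == 2L)
  if (range[1] >= range[2]) stop("region_scheme: invalid range")
  if (any(diff(boundaries) <= 0))
    stop("region_scheme: boundaries must be strictly increasing")
  if (any(boundaries <= range[1]) || any(boundaries >= range[2]))
    stop("region_scheme: boundaries must be interior to range")
  structure(list(n_regions = length(boundaries) + 1L,
                 boundaries = as.numeric(boundaries),
                 range = as.numeric(range)),
            class = "region_scheme")
}

#' Equal-width region scheme from observed responses
#'
#' Builds the default segmentation used by the data-tuning stage: nine
#' equal-width conductance regions spanning the observed G_max range over
#' all channels, widened by a small margin so extreme observations fall
#' strictly inside. Boundaries are shared across channels.
#'
#' @param responses response data frame (needs column `gmax_uS`) or a
#'   numeric vector of conductances.
#' @param n_regions number of regions (default 9).
#' @param margin fractional widening of the observed range on each side
#'   (default 0.005, i.e. 0.5%).
#' @return A [region_scheme()].
#' @export
make_region_scheme <- function(responses, n_regions = 9L, margin = 0.005) {
  g <- if (is.data.frame(responses)) responses$gmax_uS else as.numeric(responses)
  if (length(g) == 0) stop("make_region_scheme: no responses")
  r <- range(g)
  if (diff(r) <= 0)
    stop("make_region_scheme: degenerate response range (all values equal)")
  eps <- margin * diff(r)
  lo <- r[1] - eps
  hi <- r[2] + eps
  edges <- seq(lo, hi, length.out = n_regions + 1L)
  region_scheme(edges[-c(1L, n_regions + 1L)], c(lo, hi))
}

#' Region index of conductance values
#'
#' @param scheme a [region_scheme()].
#' @param g conductance value(s) (uS). Values outside the scheme range are
#'   clamped to the boundary region with a warning.
#' @return Integer region indices in `1..n_regions`.
#' @export
assign_region <- function(scheme, g) {
  stopifnot(inherits(scheme, "region_scheme"))
  if (any(g < scheme$range[1]) || any(g > scheme$range[2]))
    warning("assign_region: conductance outside scheme range; clamped")
  edges <- c(scheme$range[1], scheme$boundaries, scheme$range[2])
  findInterval(g, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Combinatorial odor pattern
#'
#' A binary regions-by-channels grid with exactly one active region per
#' channel column, plus a class label. Flattened column-major it is the
#' input vector of the pattern-recognition network (length 27 for the
#' default 9 x 3 grid).
#'
#' @param grid binary matrix (regions x channels), one 1 per column.
#' @param label class label string.
#' @return An object of class `odor_pattern`.
#' @export
odor_pattern <- function(grid, label) {
  stopifnot(is.matrix(grid), all(grid %in% c(0, 1)))
  if (any(colSums(grid) != 1))
    stop("odor_pattern: each channel column must have exactly one active region")
  structure(list(grid = grid, label = as.character(label)),
            class = "odor_pattern")
}

#' @export
format.odor_pattern <- function(x, ...) {
  art <- apply(x$grid, 1, paste, collapse = "")
  paste(c(paste0("# ", x$label), art), collapse = "\n")
}

#' @export
print.odor_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Refine a three-channel response into a binary pattern
#'
#' Maps one G_max value per channel onto the region grid: channel `c` gets a
#' single 1 in the row of the region containing its conductance.
#'
#' @param gmax named (or ordered) numeric vector, one G_max per channel in
#'   the fixed channel order.
#' @param scheme a [region_scheme()].
#' @param label class label attached to the pattern.
#' @param channels channel names used for grid column names.
#' @return An [odor_pattern()].
#' @export
refine_pattern <- function(gmax, scheme, label = "",
                           channels = names(gmax)) {
  stopifnot(inherits(scheme, "region_scheme"), is.numeric(gmax))
  k <- length(gmax)
  grid <- matrix(0L, scheme$n_regions, k,
                 dimnames = list(NULL, channels))
  rows <- assign_region(scheme, gmax)
  grid[cbind(rows, seq_len(k))] <- 1L
  odor_pattern(grid, label)
}

#' Pattern dataset
#'
#' @param patterns list of [odor_pattern()] objects.
#' @param class_names ordered class labels; every pattern label must occur in
#'   it and every class must be represented.
#' @param split `"train"` or `"inference"`.
#' @return An object of class `pattern_dataset`.
#' @export
pattern_dataset <- function(patterns, class_names,
                            split = c("train", "inference")) {
  split <- match.arg(split)
  labs <- vapply(patterns, function(p) p$label, "")
  if (!all(labs %in% class_names))
    stop("pattern_dataset: pattern label not in class_names")
  if (!all(class_names %in% labs))
    stop("pattern_dataset: every class needs at least one pattern")
  structure(list(patterns = patterns, class_names = class_names, split = split),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("Pattern dataset (%s): %d patterns, %d classes\n",
              x$split, length(x$patterns), length(x$class_names)))
  invisible(x)
}

#' @export
length.pattern_dataset <- function(x) length(x$patterns)

#' Flatten a pattern dataset to a design matrix
#'
#' @param dataset a [pattern_dataset()].
#' @return List with `x` (inputs x patterns binary matrix, column-major
#'   flattening of each grid) and `y` (integer class indices into
#'   `dataset$class_names`).
#' @export
dataset_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  x <- vapply(dataset$patterns, function(p) as.numeric(p$grid),
              numeric(length(dataset$patterns[[1]]$grid)))
  y <- match(vapply(dataset$patterns, function(p) p$label, ""),
             dataset$class_names)
  list(x = x, y = y)
}

#' Default class compositions
#'
#' The single-odorant task uses the four SCFAs; the mixed task uses nine
#' equimolar mixture classes: all six two-odorant mixtures plus the first
#' three of the four three-odorant mixtures in enumeration order
#' (PA+BA+VA, PA+BA+HA, PA+VA+HA), matching the nine-output mixed network.
#' The list is a plain argument everywhere downstream, never hard-coded.
#'
#' @param task `"single"` or `"mixed"`.
#' @param odorants odorant identifiers.
#' @return Named list of composition vectors.
#' @export
default_classes <- function(task = c("single", "mixed"),
                            odorants = c("PA", "BA", "VA", "HA")) {
  task <- match.arg(task)
  if (task == "single") {
    cls <- lapply(odorants, function(o) stats::setNames(1, o))
  } else {
    cls <- c(enumerate_mixtures(odorants, 2L),
             enumerate_mixtures(odorants, 3L)[1:3])
  }
  names(cls) <- vapply(cls, function(cm) paste(names(cm), collapse = "+"), "")
  cls
}

.split_counts <- function(n_total, k) {
  n <- rep(n_total %/% k, k)
  r <- n_total %% k
  if (r > 0) n[seq_len(r)] <- n[seq_len(r)] + 1L
  n
}

#' Build train and inference pattern datasets
#'
#' Generates seeded noisy responses for each class composition at the given
#' total concentration, derives the shared region scheme from the training
#' responses (unless one is supplied), and refines every response triple
#' into a binary pattern. Train and inference sets are drawn with
#' independent derived seeds. Totals are split as evenly as possible across
#' classes (per-class counts differ by at most one).
#'
#' @param profile an [affinity_profile()].
#' @param classes named list of composition vectors (see
#'   [default_classes()]).
#' @param n_train,n_infer total pattern counts (defaults 216/40 for the
#'   four-class single task; use 2194/366 for the nine-class mixed task).
#' @param total_ppm total concentration of every sample (ppm).
#' @param seed integer seed; stage seeds are derived from it.
#' @param scheme optional [region_scheme()] override.
#' @param n_regions regions used when fitting the scheme.
#' @return List with `train` and `infer` [pattern_dataset()]s and the
#'   `scheme` used.
#' @export
build_datasets <- function(profile, classes = default_classes("single"),
                           n_train = 216L, n_infer = 40L,
                           total_ppm = profile$ref_ppm, seed = 1L,
                           scheme = NULL, n_regions = 9L) {
  stopifnot(inherits(profile, "affinity_profile"), length(classes) >= 1)
  k <- length(classes)
  gen <- function(n_total, base_seed) {
    n_per <- .split_counts(n_total, k)
    out <- vector("list", k)
    for (ci in seq_len(k)) {
      rr <- sample_responses(profile, classes[[ci]], total_ppm,
                             n_replicates = n_per[ci],
                             seed = derive_seed(base_seed, names(classes)[ci]),
                             sample_prefix = paste0(names(classes)[ci], "_"))
      out[[ci]] <- rr
    }
    out
  }
  tr_resp <- gen(n_train, derive_seed(seed, "train"))
  te_resp <- gen(n_infer, derive_seed(seed, "inference"))
  if (is.null(scheme))
    scheme <- make_region_scheme(do.call(rbind, tr_resp), n_regions = n_regions)
  to_patterns <- function(resp_list) {
    pats <- list()
    for (ci in seq_len(k)) {
      rr <- resp_list[[ci]]
      wide <- split(rr$gmax_uS, rr$channel)[profile$channels]
      gm <- do.call(cbind, wide)  # replicates x channels
      for (i in seq_len(nrow(gm)))
        pats[[length(pats) + 1L]] <- refine_pattern(
          stats::setNames(gm[i, ], profile$channels), scheme,
          label = names(classes)[ci])
    }
    pats
  }
  list(train = pattern_dataset(to_patterns(tr_resp), names(classes), "train"),
       infer = pattern_dataset(to_patterns(te_resp), names(classes), "inference"),
       scheme = scheme)
}
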