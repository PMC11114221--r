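#' Derive a stage seed from a global seed
#'
#' Deterministic hash of `(seed, stage)` into a positive 32-bit integer, so
#' one user-facing seed drives every pipeline stage while keeping stages
#' statistically independent and individually replayable.
#'
#' @param seed integer global seed.
#' @param stage stage name string.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647 + 1)
}

.fmt <- function(x) signif(x, 6)

#' Read and write device parameters as JSON
#'
#' Keys: `g_min_uS`, `g_max_uS`, `p_max`, `a_p`, `a_d`.
#'
#' @param params a [device_params()].
#' @param path file path.
#' @return `read_device_params()` returns a [device_params()];
#'   `write_device_params()` returns `path` invisibly.
#' @export
write_device_params <- function(params, path) {
  stopifnot(inherits(params, "device_params"))
  jsonlite::write_json(list(g_min_uS = params$g_min, g_max_uS = params$g_max,
                            p_max = params$p_max, a_p = params$a_p,
                            a_d = params$a_d),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_device_params
#' @export
read_device_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("g_min_uS", "g_max_uS", "p_max", "a_p", "a_d")
  if (!all(need %in% names(j)))
    stop("read_device_params: missing keys: ",
         paste(setdiff(need, names(j)), collapse = ", "))
  device_params(j$g_min_uS, j$g_max_uS, j$p_max, j$a_p, j$a_d)
}

#' Read and write conductance traces as delimited text
#'
#' Three tab-separated columns: `phase`, `pulse`, `conductance_uS`.
#'
#' @param trace a `conductance_trace` data frame.
#' @param path file path.
#' @return `read_trace()` returns the trace; `write_trace()` returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  out <- trace
  out$conductance_uS <- .fmt(out$conductance_uS)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phase", "pulse", "conductance_uS")
  if (!all(need %in% names(d)))
    stop("read_trace: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  structure(d, class = c("conductance_trace", "data.frame"))
}

#' Read and write affinity profiles as JSON
#'
#' @param profile an [affinity_profile()].
#' @param path file path.
#' @return `read_profile()` returns an [affinity_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "affinity_profile"))
  jsonlite::write_json(list(channels = profile$channels,
                            odorants = profile$odorants,
                            mean_gmax = profile$mean_gmax,
                            noise_sd = profile$noise_sd,
                            baseline_gmax = as.numeric(profile$baseline_gmax),
                            ref_ppm = profile$ref_ppm),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v) {
    m <- if (is.matrix(v)) v else do.call(rbind, v)
    dimnames(m) <- list(j$channels, j$odorants)
    m
  }
  m <- as_mat(j$mean_gmax)
  s <- as_mat(j$noise_sd)
  affinity_profile(m, s, j$baseline_gmax, j$ref_ppm)
}

#' Read and write response tables as delimited text
#'
#' Tab-separated columns: `sample_id`, `composition` (odorant:fraction;...),
#' `total_ppm`, `channel`, `gmax_uS`.
#'
#' @param responses response data frame from [sample_responses()].
#' @param path file path.
#' @return `read_responses()` returns the data frame.
#' @export
write_responses <- function(responses, path) {
  out <- responses
  out$gmax_uS <- .fmt(out$gmax_uS)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "composition", "total_ppm", "channel", "gmax_uS")
  if (!all(need %in% names(d)))
    stop("read_responses: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Read and write region schemes as JSON
#'
#' @param scheme a [region_scheme()].
#' @param path file path.
#' @return `read_scheme()` returns a [region_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "region_scheme"))
  jsonlite::write_json(list(n_regions = scheme$n_regions,
                            boundaries = scheme$boundaries,
                            range = scheme$range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_scheme(j$boundaries, j$range)
}

#' Read and write pattern datasets as JSON lines
#'
#' One JSON object per line: `{"label": ..., "grid": [27 zeros/ones]}`,
#' grid flattened column-major (regions fastest).
#'
#' @param dataset a [pattern_dataset()].
#' @param path file path.
#' @param n_regions grid row count used when reading back.
#' @param split split tag used when reading back.
#' @return `read_patterns()` returns a [pattern_dataset()].
#' @export
write_patterns <- function(dataset, path) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  lines <- vapply(dataset$patterns, function(p) {
    jsonlite::toJSON(list(label = p$label, grid = as.integer(p$grid)),
                     auto_unbox = TRUE)
  }, "")
  header <- jsonlite::toJSON(list(class_names = dataset$class_names,
                                  split = dataset$split))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path, n_regions = 9L, split = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("read_patterns: file has no patterns")
  header <- jsonlite::fromJSON(lines[1])
  pats <- lapply(lines[-1], function(ln) {
    j <- jsonlite::fromJSON(ln)
    grid <- matrix(as.integer(j$grid), nrow = n_regions)
    odor_pattern(grid, j$label)
  })
  pattern_dataset(pats, unlist(header$class_names),
                  if (is.null(split)) unlist(header$split) else split)
}

#' Read and write accuracy trajectories as delimited text
#'
#' Two tab-separated columns: `step`, `accuracy_pct`.
#'
#' @param trajectory data frame from [train_ann()].
#' @param path file path.
#' @return `read_trajectory()` returns the data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- trajectory
  out$accuracy_pct <- .fmt(out$accuracy_pct)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("step", "accuracy_pct") %in% names(d)))
    stop("read_trajectory: missing columns")
  d
}

#' Write a trained network state as JSON
#'
#' Conductance arrays row-major, layer-tagged, with the device and
#' architecture alongside.
#'
#' @param state an [ann_state][init_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ann_state <- function(state, path) {
  stopifnot(inherits(state, "ann_state"))
  cfg <- state$config
  jsonlite::write_json(list(
    architecture = c(cfg$n_input, cfg$n_hidden, cfg$n_output),
    step = state$step,
    device = list(g_min_uS = state$device$g_min, g_max_uS = state$device$g_max,
                  p_max = state$device$p_max, a_p = state$device$a_p,
                  a_d = state$device$a_d),
    layer1 = list(g_plus = state$layer1$g_plus, g_minus = state$layer1$g_minus),
    layer2 = list(g_plus = state$layer2$g_plus, g_minus = state$layer2$g_minus)
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

.validators <- list(
  device_json = function(path) read_device_params(path),
  profile_json = function(path) read_profile(path),
  scheme_json = function(path) read_scheme(path),
  responses_tsv = function(path) {
    d <- read_responses(path)
    if (any(!is.finite(d$gmax_uS))) stop("non-finite gmax_uS")
    for (i in seq_len(nrow(d))) .chk_comp_string(d$composition[i])
    d
  },
  patterns_jsonl = function(path) {
    ds <- read_patterns(path)
    for (p in ds$patterns)
      if (any(colSums(p$grid) != 1))
        stop("pattern grid column does not sum to 1")
    ds
  },
  trace_tsv = function(path) read_trace(path),
  trajectory_tsv = function(path) {
    d <- read_trajectory(path)
    if (any(d$accuracy_pct < 0 | d$accuracy_pct > 100))
      stop("accuracy outside [0, 100]")
    d
  }
)

.chk_comp_string <- function(s) {
  comp <- parse_composition(s)
  if (any(!is.finite(comp)) || any(comp <= 0) || abs(sum(comp) - 1) > 1e-6)
    stop("invalid composition: ", s)
  invisible(comp)
}

.guess_kind <- function(path) {
  base <- basename(path)
  if (grepl("\\.jsonl$", base)) return("patterns_jsonl")
  if (grepl("device", base) && grepl("\\.json$", base)) return("device_json")
  if (grepl("profile", base) && grepl("\\.json$", base)) return("profile_json")
  if (grepl("scheme", base) && grepl("\\.json$", base)) return("scheme_json")
  if (grepl("respons", base)) return("responses_tsv")
  if (grepl("traject", base)) return("trajectory_tsv")
  if (grepl("trace", base)) return("trace_tsv")
  NA_character_
}

#' Validate pipeline files
#'
#' Schema-checks every supported file format (device/profile/scheme JSON,
#' response and trajectory tables, pattern JSON-lines, traces), reporting
#' per-file pass/fail with a message. Reports content errors rather than
#' throwing.
#'
#' @param paths character vector of file paths.
#' @param kinds optional format kinds (one of
#'   `names(aosim:::.validators)`); guessed from filenames when `NULL`.
#' @return Data frame with columns `file`, `kind`, `ok`, `message`.
#' @export
validate_files <- function(paths, kinds = NULL) {
  if (is.null(kinds)) kinds <- vapply(paths, .guess_kind, "")
  stopifnot(length(kinds) == length(paths))
  res <- lapply(seq_along(paths), function(i) {
    kind <- kinds[i]
    if (!file.exists(paths[i]))
      return(data.frame(file = paths[i], kind = kind, ok = FALSE,
                        message = "file does not exist"))
    if (is.na(kind) || !kind %in% names(.validators))
      return(data.frame(file = paths[i], kind = NA, ok = FALSE,
                        message = "unrecognized file kind"))
    msg <- "ok"
    ok <- TRUE
    tryCatch(.validators[[kind]](paths[i]),
             error = function(e) {
               ok <<- FALSE
               msg <<- conditionMessage(e)
             })
    data.frame(file = paths[i], kind = kind, ok = ok, message = msg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full sensing-to-recognition pipeline
#'
#' Synthesize responses from the affinity profile, refine them into 9 x 3
#' binary patterns, train the device-aware network, and compute the summary
#' statistics (final and peak accuracy, PCA variance fractions of the
#' single-odorant responses, per-channel/odorant detection limits). All
#' artifacts are written under `out_dir`; a second run with the same
#' configuration reproduces them byte-identically.
#'
#' @param task `"single"` (27 x 14 x 4 network, 216/40 patterns) or
#'   `"mixed"` (27 x 27 x 9, 2194/366 patterns).
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed; all stage seeds are derived from it.
#' @param profile an [affinity_profile()].
#' @param device a [device_params()].
#' @param total_steps training steps (defaults: 1000 single, 150000 mixed).
#' @param classes class composition list (default per task).
#' @param n_train,n_infer dataset sizes (defaults per task).
#' @return List with `trajectory`, `final_accuracy`, `peak_accuracy`,
#'   `pca_explained`, `detection_limits`, `paths` of written artifacts.
#' @export
run_pipeline <- function(task = c("single", "mixed"), out_dir = tempfile("aosim_"),
                         seed = 1L, profile = default_affinity_profile(),
                         device = device_params(), total_steps = NULL,
                         classes = NULL, n_train = NULL, n_infer = NULL) {
  task <- match.arg(task)
  if (is.null(classes)) classes <- default_classes(task)
  if (is.null(n_train)) n_train <- if (task == "single") 216L else 2194L
  if (is.null(n_infer)) n_infer <- if (task == "single") 40L else 366L
  if (is.null(total_steps)) total_steps <- if (task == "single") 1000L else 150000L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- build_datasets(profile, classes, n_train = n_train, n_infer = n_infer,
                       seed = derive_seed(seed, paste0("datasets_", task)))
  cfg <- if (task == "single") {
    ann_config(n_hidden = 14L, n_output = length(classes),
               total_steps = as.integer(total_steps))
  } else {
    ann_config(n_hidden = 27L, n_output = length(classes),
               total_steps = as.integer(total_steps))
  }
  st <- init_network(cfg, device, seed = derive_seed(seed, "init"))
  fit <- train_ann(st, ds$train, ds$infer, seed = derive_seed(seed, "train"))
  traj <- fit$trajectory
  # summary statistics on the single-odorant response structure
  wide <- do.call(rbind, lapply(profile$odorants, function(o) {
    rr <- sample_responses(profile, stats::setNames(1, o), n_replicates = 25L,
                           seed = derive_seed(seed, paste0("pca_", o)),
                           sample_prefix = o)
    matrix(rr$gmax_uS, ncol = length(profile$channels),
           dimnames = list(NULL, profile$channels))
  }))
  pca <- pca_responses(wide)
  lods <- do.call(rbind, lapply(profile$channels, function(ch)
    do.call(rbind, lapply(profile$odorants, function(o) {
      cal <- make_calibration(profile, ch, o,
                              seed = derive_seed(seed, paste0("cal_", ch, o)))
      data.frame(channel = ch, odorant = o, lod_ppm = detection_limit(cal))
    }))))
  paths <- list(
    profile = file.path(out_dir, "profile.json"),
    scheme = file.path(out_dir, "scheme.json"),
    device = file.path(out_dir, "device.json"),
    train = file.path(out_dir, paste0(task, "_train.jsonl")),
    infer = file.path(out_dir, paste0(task, "_inference.jsonl")),
    trajectory = file.path(out_dir, paste0(task, "_trajectory.tsv")),
    state = file.path(out_dir, paste0(task, "_state.json")),
    report = file.path(out_dir, paste0(task, "_report.json"))
  )
  write_profile(profile, paths$profile)
  write_scheme(ds$scheme, paths$scheme)
  write_device_params(device, paths$device)
  write_patterns(ds$train, paths$train)
  write_patterns(ds$infer, paths$infer)
  write_trajectory(traj, paths$trajectory)
  write_ann_state(fit$state, paths$state)
  report <- list(task = task, seed = seed,
                 n_train = length(ds$train), n_infer = length(ds$infer),
                 total_steps = total_steps,
                 final_accuracy_pct = traj$accuracy_pct[nrow(traj)],
                 peak_accuracy_pct = max(traj$accuracy_pct),
                 pca_explained = as.numeric(pca$explained),
                 checksums = vapply(unlist(paths[c("train", "infer", "trajectory")]),
                                    function(p) as.character(sum(utf8ToInt(paste(readLines(p), collapse = "\n")))),
                                    ""))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
  list(trajectory = traj,
       final_accuracy = report$final_accuracy_pct,
       peak_accuracy = report$peak_accuracy_pct,
       pca_explained = report$pca_explained,
       detection_limits = lods,
       paths = paths)
}
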