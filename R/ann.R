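#' Configuration of the device-aware two-layer perceptron
#'
#' The single-odorant network is 27 x 14 x 4 (27 inputs for the flattened
#' 9 x 3 pattern, 14 hidden neurons, 4 outputs); the mixed-odorant network
#' is 27 x 27 x 9. Learning rates default to 0.03 for the first synaptic
#' weight matrix and 0.0001 for the second. One epoch is 100 training steps;
#' inference accuracy is recorded once per epoch.
#'
#' @param n_input input width (27 when consuming 9 x 3 patterns).
#' @param n_hidden hidden-layer size (14 single-odorant default; 27 mixed).
#' @param n_output number of classes (4 single default; 9 mixed).
#' @param lr_layer1,lr_layer2 learning rates of the two weight matrices.
#' @param steps_per_epoch training steps between accuracy evaluations.
#' @param total_steps default training length.
#' @param pulse_cap maximum programming pulses per synapse per step.
#' @param refresh_margin fraction of the conductance span below saturation at
#'   which a differential pair is re-programmed to its minimal-pulse
#'   configuration.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(n_input = 27L, n_hidden = 14L, n_output = 4L,
                       lr_layer1 = 0.03, lr_layer2 = 0.0001,
                       steps_per_epoch = 100L, total_steps = 1000L,
                       pulse_cap = 10L, refresh_margin = 0.01) {
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1,
            lr_layer1 > 0, lr_layer2 > 0, steps_per_epoch >= 1,
            total_steps >= 0, pulse_cap >= 1,
            refresh_margin > 0, refresh_margin < 1)
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output),
                 lr_layer1 = lr_layer1, lr_layer2 = lr_layer2,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 total_steps = as.integer(total_steps),
                 pulse_cap = as.integer(pulse_cap),
                 refresh_margin = refresh_margin),
            class = "ann_config")
}

#' Differential-pair weight mapping
#'
#' Each synapse is a pair of bounded conductances; its signed, dimensionless
#' weight is `(g_plus - g_minus) / (g_max - g_min)`, in `[-1, 1]`.
#'
#' @param g_plus,g_minus conductances (uS) within the device bounds.
#' @param device a [device_params()].
#' @return Weight(s) in `[-1, 1]`.
#' @export
weight_of <- function(g_plus, g_minus, device) {
  stopifnot(inherits(device, "device_params"))
  tol <- 1e-9 * (device$g_max - device$g_min)
  if (any(g_plus < device$g_min - tol) || any(g_plus > device$g_max + tol) ||
      any(g_minus < device$g_min - tol) || any(g_minus > device$g_max + tol))
    stop("weight_of: conductance outside [g_min, g_max]")
  (g_plus - g_minus) / (device$g_max - device$g_min)
}

# snap conductances to the nearest integer pulse position on the LTP curve
.snap_to_pulse <- function(device, g) {
  p <- round(ltp_pulse_position(device, pmin(pmax(g, device$g_min), device$g_max)))
  g_ltp(device, pmin(p, device$p_max))
}

# program a weight matrix into differential pairs at minimal pulse positions
.program_pairs <- function(device, w) {
  span <- device$g_max - device$g_min
  gp <- ifelse(w >= 0, device$g_min + w * span, device$g_min)
  gm <- ifelse(w < 0, device$g_min - w * span, device$g_min)
  list(g_plus = .snap_to_pulse(device, gp), g_minus = .snap_to_pulse(device, gm))
}

#' Initialize the device-aware network
#'
#' Hidden-layer pairs start near zero weight (uniform in
#' `[-init_hidden, init_hidden]`): a blank slate on which training imprints
#' class signatures. The output layer, whose learning rate makes it
#' essentially a fixed readout, is programmed to a full-scale random
#' orthogonal class code (QR of a seeded Gaussian matrix, columns scaled to
#' the norm of a uniform full-range column, clipped to `[-1, 1]`), so the
#' error signals fed back for different classes do not interfere. All
#' conductances are snapped to integer pulse positions on the LTP curve.
#' Deterministic given `seed`.
#'
#' @param config an [ann_config()].
#' @param device a [device_params()].
#' @param seed integer RNG seed.
#' @param init_hidden half-width of the hidden-layer initial weight range.
#' @return An object of class `ann_state`: conductance-pair matrices
#'   `layer1`/`layer2` (`g_plus`, `g_minus`), the device, the config, and a
#'   `step` counter.
#' @export
init_network <- function(config, device = device_params(), seed = 1L,
                         init_hidden = 0.05) {
  stopifnot(inherits(config, "ann_config"), inherits(device, "device_params"))
  set.seed(as.integer(seed))
  w1 <- matrix(stats::runif(config$n_input * config$n_hidden,
                            -init_hidden, init_hidden),
               config$n_input, config$n_hidden)
  q <- qr.Q(qr(matrix(stats::rnorm(config$n_hidden * config$n_output),
                      config$n_hidden, config$n_output)))
  w2 <- pmin(pmax(q * sqrt(config$n_hidden / 3), -1), 1)
  structure(list(layer1 = .program_pairs(device, w1),
                 layer2 = .program_pairs(device, w2),
                 device = device, config = config, step = 0L),
            class = "ann_state")
}

#' @export
print.ann_state <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Device-aware ANN %d x %d x %d (synapse count, product convention: %d), step %d\n",
              cfg$n_input, cfg$n_hidden, cfg$n_output,
              cfg$n_input * cfg$n_hidden * cfg$n_output, x$step))
  invisible(x)
}

#' Current weight matrices of a network state
#'
#' @param state an [ann_state][init_network()].
#' @return List of the two weight matrices `w1`, `w2`.
#' @export
ann_weights <- function(state) {
  stopifnot(inherits(state, "ann_state"))
  list(w1 = weight_of(state$layer1$g_plus, state$layer1$g_minus, state$device),
       w2 = weight_of(state$layer2$g_plus, state$layer2$g_minus, state$device))
}

#' Forward pass
#'
#' Bipolar two-layer perceptron: `h = tanh(W1' x)`, `y = tanh(W2' h)`.
#' The predicted class is the arg-max output, ties broken toward the lowest
#' class index.
#'
#' @param state an [ann_state][init_network()].
#' @param input an [odor_pattern()], a numeric input vector of length
#'   `n_input`, or an inputs-by-patterns matrix.
#' @return List with `hidden`, `output` (activations in `(-1, 1)`) and
#'   `prediction` (integer class index per pattern).
#' @export
ann_forward <- function(state, input) {
  stopifnot(inherits(state, "ann_state"))
  x <- if (inherits(input, "odor_pattern")) as.numeric(input$grid) else input
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != state$config$n_input)
    stop("ann_forward: input width does not match n_input")
  w <- ann_weights(state)
  h <- tanh(crossprod(w$w1, x))
  y <- tanh(crossprod(w$w2, h))
  list(hidden = h, output = y,
       prediction = max.col(t(y), ties.method = "first"))
}

# backprop deltas for one pattern under the 1/2 sum-of-squares loss with
# bipolar (+1/-1) one-hot targets
.ann_grads <- function(w1, w2, x, target, lr1, lr2) {
  h <- tanh(crossprod(w1, x))
  y <- tanh(crossprod(w2, h))
  d_out <- (y - target) * (1 - y^2)
  d_hid <- (w2 %*% d_out) * (1 - h^2)
  list(dw1 = -lr1 * (x %*% t(d_hid)), dw2 = -lr2 * (h %*% t(d_out)))
}

# apply a desired weight change to one layer's pairs by pulse-quantized
# potentiation along the LTP curve; expectation-preserving stochastic
# rounding; refresh pairs approaching saturation
.apply_deltas <- function(pair, dw, device, cap, refresh_margin) {
  span <- device$g_max - device$g_min
  a <- device$a_p
  B <- (device$g_max - device$g_min) / (1 - exp(-device$p_max / a))
  pos <- dw > 0
  target_g <- ifelse(pos, pair$g_plus, pair$g_minus)
  frac <- pmin(pmax((target_g - device$g_min) / B, 0), 1 - 1e-12)
  p <- -a * log(1 - frac)
  slope <- B / a * exp(-p / a)
  n_real <- abs(dw) * span / slope
  n_int <- floor(n_real)
  n_pulse <- pmin(n_int + (stats::runif(length(n_real)) < (n_real - n_int)), cap)
  g_new <- B * (1 - exp(-pmin(p + n_pulse, device$p_max) / a)) + device$g_min
  pair$g_plus[pos] <- g_new[pos]
  pair$g_minus[!pos] <- g_new[!pos]
  sat <- pmax(pair$g_plus, pair$g_minus) > device$g_max - refresh_margin * span
  if (any(sat)) {
    w <- (pair$g_plus[sat] - pair$g_minus[sat]) / span
    p_hi <- round(-a * log(1 - pmin(pmax(abs(w) * span / B, 0), 1 - 1e-12)))
    g_hi <- B * (1 - exp(-pmin(p_hi, device$p_max) / a)) + device$g_min
    pair$g_plus[sat] <- ifelse(w >= 0, g_hi, device$g_min)
    pair$g_minus[sat] <- ifelse(w >= 0, device$g_min, g_hi)
  }
  pair
}

#' One training step
#'
#' Backpropagates the squared-error gradient for a single pattern and
#' realizes the desired weight changes on the conductance pairs.
#' In `"device"` mode each change is converted to an integer number of
#' potentiation pulses on `g_plus` (for positive changes) or `g_minus`
#' (negative), using the local LTP slope at the synapse's current pulse
#' position, with expectation-preserving stochastic rounding and a per-step
#' pulse cap; pairs nearing saturation are refreshed to the minimal-pulse
#' configuration carrying the same weight. In `"ideal"` mode (the
#' continuous-limit oracle) the exact conductance change `dw * (g_max -
#' g_min)` is applied with no quantization, only clipping at the bounds.
#'
#' @param state an [ann_state][init_network()].
#' @param input pattern or input vector (see [ann_forward()]).
#' @param class_index integer target class in `1..n_output`.
#' @param mode `"device"` (pulse-quantized) or `"ideal"` (continuous).
#' @return The updated `ann_state`.
#' @export
train_step <- function(state, input, class_index, mode = c("device", "ideal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "ann_state"))
  x <- if (inherits(input, "odor_pattern")) as.numeric(input$grid) else input
  cfg <- state$config
  stopifnot(length(x) == cfg$n_input,
            class_index >= 1, class_index <= cfg$n_output)
  target <- rep(-1, cfg$n_output)
  target[class_index] <- 1
  w <- ann_weights(state)
  gr <- .ann_grads(w$w1, w$w2, matrix(x, ncol = 1L), target,
                   cfg$lr_layer1, cfg$lr_layer2)
  if (mode == "device") {
    state$layer1 <- .apply_deltas(state$layer1, gr$dw1, state$device,
                                  cfg$pulse_cap, cfg$refresh_margin)
    state$layer2 <- .apply_deltas(state$layer2, gr$dw2, state$device,
                                  cfg$pulse_cap, cfg$refresh_margin)
  } else {
    span <- state$device$g_max - state$device$g_min
    clip <- function(g) pmin(pmax(g, state$device$g_min), state$device$g_max)
    for (ly in c("layer1", "layer2")) {
      dw <- if (ly == "layer1") gr$dw1 else gr$dw2
      pos <- dw > 0
      pr <- state[[ly]]
      pr$g_plus[pos] <- clip(pr$g_plus[pos] + dw[pos] * span)
      pr$g_minus[!pos] <- clip(pr$g_minus[!pos] - dw[!pos] * span)
      state[[ly]] <- pr
    }
  }
  state$step <- state$step + 1L
  state
}

#' Classification accuracy on a dataset
#'
#' @param state an [ann_state][init_network()].
#' @param dataset a [pattern_dataset()] or a list with elements `x`
#'   (inputs x patterns) and `y` (class indices).
#' @return Accuracy in percent: `100 * correct / total`.
#' @export
evaluate_ann <- function(state, dataset) {
  d <- if (inherits(dataset, "pattern_dataset")) dataset_matrix(dataset) else dataset
  pred <- ann_forward(state, d$x)$prediction
  100 * mean(pred == d$y)
}

#' Train the network and record the accuracy trajectory
#'
#' Each step consumes one training pattern sampled uniformly with
#' replacement (seeded); inference-set accuracy is recorded every
#' `steps_per_epoch` steps. The loop is run on plain matrices for speed and
#' is bit-reproducible given `(seed, datasets, config, device)`.
#'
#' @param state an [ann_state][init_network()].
#' @param train_set,infer_set [pattern_dataset()]s (or `x`/`y` lists).
#' @param total_steps training steps (default from the config).
#' @param seed integer RNG seed for pattern sampling and pulse rounding.
#' @param mode `"device"` or `"ideal"` (see [train_step()]).
#' @return List with `trajectory` (data frame `step`, `accuracy_pct`) and the
#'   final `state`.
#' @export
train_ann <- function(state, train_set, infer_set,
                      total_steps = state$config$total_steps, seed = 1L,
                      mode = c("device", "ideal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "ann_state"))
  tr <- if (inherits(train_set, "pattern_dataset")) dataset_matrix(train_set) else train_set
  te <- if (inherits(infer_set, "pattern_dataset")) dataset_matrix(infer_set) else infer_set
  cfg <- state$config
  dev <- state$device
  if (nrow(tr$x) != cfg$n_input || nrow(te$x) != cfg$n_input)
    stop("train_ann: dataset width does not match n_input")
  if (max(tr$y) > cfg$n_output) stop("train_ann: more classes than outputs")
  span <- dev$g_max - dev$g_min
  targets <- 2 * diag(cfg$n_output) - 1
  set.seed(as.integer(seed))
  n_ev <- total_steps %/% cfg$steps_per_epoch
  steps_out <- numeric(n_ev + 1L)
  acc_out <- numeric(n_ev + 1L)
  l1 <- state$layer1; l2 <- state$layer2
  eval_acc <- function() {
    w1 <- (l1$g_plus - l1$g_minus) / span
    w2 <- (l2$g_plus - l2$g_minus) / span
    y <- tanh(crossprod(w2, tanh(crossprod(w1, te$x))))
    100 * mean(max.col(t(y), ties.method = "first") == te$y)
  }
  steps_out[1L] <- state$step
  acc_out[1L] <- eval_acc()
  k <- 1L
  n_train <- ncol(tr$x)
  if (total_steps > 0) {
    for (s in seq_len(total_steps)) {
      i <- sample.int(n_train, 1L)
      x <- tr$x[, i, drop = FALSE]
      w1 <- (l1$g_plus - l1$g_minus) / span
      w2 <- (l2$g_plus - l2$g_minus) / span
      gr <- .ann_grads(w1, w2, x, targets[, tr$y[i]],
                       cfg$lr_layer1, cfg$lr_layer2)
      if (mode == "device") {
        l1 <- .apply_deltas(l1, gr$dw1, dev, cfg$pulse_cap, cfg$refresh_margin)
        l2 <- .apply_deltas(l2, gr$dw2, dev, cfg$pulse_cap, cfg$refresh_margin)
      } else {
        clip <- function(g) pmin(pmax(g, dev$g_min), dev$g_max)
        for (ly in 1:2) {
          dw <- if (ly == 1) gr$dw1 else gr$dw2
          pr <- if (ly == 1) l1 else l2
          pos <- dw > 0
          pr$g_plus[pos] <- clip(pr$g_plus[pos] + dw[pos] * span)
          pr$g_minus[!pos] <- clip(pr$g_minus[!pos] - dw[!pos] * span)
          if (ly == 1) l1 <- pr else l2 <- pr
        }
      }
      if (s %% cfg$steps_per_epoch == 0L) {
        k <- k + 1L
        steps_out[k] <- state$step + s
        acc_out[k] <- eval_acc()
      }
    }
  }
  state$layer1 <- l1
  state$layer2 <- l2
  state$step <- state$step + as.integer(total_steps)
  traj <- data.frame(step = steps_out[seq_len(k)],
                     accuracy_pct = acc_out[seq_len(k)])
  list(trajectory = traj, state = state)
}

#' Final accuracy as a function of device nonlinearity
#'
#' Trains otherwise identical networks that differ only in their device
#' parameters and reports the final inference accuracy of each, isolating
#' the effect of conductance-update nonlinearity on learning (near-linear
#' devices retain fine weight resolution across the range; strongly
#' nonlinear ones compress most of it into the first pulses).
#'
#' @param devices list of [device_params()] objects.
#' @param train_set,infer_set [pattern_dataset()]s.
#' @param config an [ann_config()].
#' @param seed integer seed shared by all runs (paired comparison).
#' @return Data frame with `a_p`, `a_d` and `final_accuracy_pct`, one row per
#'   device.
#' @export
linearity_sweep <- function(devices, train_set, infer_set,
                            config = ann_config(), seed = 1L) {
  stopifnot(is.list(devices), length(devices) >= 2)
  res <- lapply(devices, function(dv) {
    st <- init_network(config, dv, seed = seed)
    fit <- train_ann(st, train_set, infer_set, seed = derive_seed(seed, "sweep"))
    data.frame(a_p = dv$a_p, a_d = dv$a_d,
               final_accuracy_pct = fit$trajectory$accuracy_pct[nrow(fit$trajectory)])
  })
  do.call(rbind, res)
}
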