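#' Specification of the tabular (naive) feature stream
#'
#' A fully connected stack over the per-segment telemetry feature vector:
#' hidden layers of 128, 64, 32 ReLU units by default, with dropout 0.5
#' after the first two. Standalone it ends in a 2-class softmax; in
#' fusion mode the final 32-unit hidden layer is the stream's embedding.
#'
#' The default input carries five values per segment — mean step distance,
#' mean computed speed, mean speed over ground, and the mean unit-circle
#' direction components. `input_dim = 4` corresponds to the strict
#' variant in which direction enters as a single scaled azimuth value.
#'
#' @param input_dim number of tabular features per segment.
#' @param hidden_dims widths of the hidden layers (last = embedding dim).
#' @param dropout dropout rate after the first two hidden layers.
#' @return a `naive_stream_spec` list.
#' @export
naive_stream_spec <- function(input_dim = 5L, hidden_dims = c(128L, 64L, 32L),
                              dropout = 0.5) {
  stopifnot(input_dim >= 1, length(hidden_dims) >= 1,
            dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropout = dropout),
            class = "naive_stream_spec")
}

#' Specification of the convolutional grid stream
#'
#' A single valid 3x3 convolution (32 filters, ReLU) over the G x G
#' binary occupancy grid, a 2x2 max-pool (identity when the conv output
#' is already 1x1, as with the 3x3 grid), a flatten, and fully connected
#' layers of 256, 64, 32 ReLU units with dropout 0.5 after the first.
#' The final 32-unit layer is the stream's embedding.
#'
#' @param extent grid cells per side (>= kernel).
#' @param filters convolution filters.
#' @param kernel convolution kernel side.
#' @param fc_dims widths of the fully connected layers (last = embedding).
#' @param dropout dropout rate after the first FC layer.
#' @return a `grid_stream_spec` list.
#' @export
grid_stream_spec <- function(extent = 3L, filters = 32L, kernel = 3L,
                             fc_dims = c(256L, 64L, 32L), dropout = 0.5) {
  stopifnot(extent >= kernel, length(fc_dims) >= 1,
            dropout >= 0, dropout < 1)
  structure(list(extent = as.integer(extent), filters = as.integer(filters),
                 kernel = as.integer(kernel), fc_dims = as.integer(fc_dims),
                 dropout = dropout),
            class = "grid_stream_spec")
}

#' Specification of the fused two-stream classifier head
#'
#' The 32-dim embeddings of the tabular and grid streams concatenate into
#' a 64-dim fused vector, refined by fully connected layers of 256, 64,
#' 32 ReLU units (dropout 0.5 after the first) and a 2-class softmax.
#'
#' @param fc_dims widths of the post-fusion fully connected layers.
#' @param dropout dropout rate after the first post-fusion layer.
#' @return a `combined_spec` list.
#' @export
combined_spec <- function(fc_dims = c(256L, 64L, 32L), dropout = 0.5) {
  stopifnot(length(fc_dims) >= 1, dropout >= 0, dropout < 1)
  structure(list(fc_dims = as.integer(fc_dims), dropout = dropout),
            class = "combined_spec")
}

#' Training configuration
#'
#' Adam with learning rate 0.001 and softmax cross-entropy over the two
#' classes; epochs and batch size are free choices of the experiment.
#'
#' @param learning_rate Adam step size.
#' @param epochs passes over the training data.
#' @param batch_size minibatch size.
#' @param seed RNG seed governing weight initialization, shuffling and
#'   dropout; fixed per run and recorded on the fitted model.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 100L,
                            batch_size = 64L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_config")
}

.mlp_layers <- function(input_dim, hidden_dims, dropout) {
  layers <- list()
  n_in <- input_dim
  for (j in seq_along(hidden_dims)) {
    layers <- c(layers, list(lay_dense(n_in, hidden_dims[j]), lay_relu()))
    if (j <= 2 && dropout > 0) layers <- c(layers, list(lay_dropout(dropout)))
    n_in <- hidden_dims[j]
  }
  layers
}

.grid_layers <- function(spec) {
  conv <- lay_conv(spec$extent, spec$filters, spec$kernel)
  pool <- lay_pool(conv$oh, spec$filters)
  flat_dim <- pool$out_oh^2 * spec$filters
  layers <- list(conv, lay_relu(), pool)
  n_in <- flat_dim
  for (j in seq_along(spec$fc_dims)) {
    layers <- c(layers, list(lay_dense(n_in, spec$fc_dims[j]), lay_relu()))
    if (j == 1 && spec$dropout > 0)
      layers <- c(layers, list(lay_dropout(spec$dropout)))
    n_in <- spec$fc_dims[j]
  }
  layers
}

.embedding_dim <- function(layers) {
  dims <- vapply(layers, function(l)
    if (!is.null(l$n_out) && l$type == "dense") l$n_out else NA_integer_,
    integer(1))
  utils::tail(dims[!is.na(dims)], 1)
}

.new_model <- function(kind, branches, head, spec) {
  m <- structure(list(kind = kind, branches = branches, head = head,
                      spec = spec, fitted = FALSE, config = NULL,
                      history = NULL),
                 class = "dg_model")
  audit_model(m)
  m
}

#' Structural audit of a built model
#'
#' Asserts the layer-by-layer contract of the architecture: stream
#' embedding dimensions, the fused dimension equal to their sum, and a
#' 2-unit classification head where one is present. Runs at build time.
#'
#' @param model a `dg_model`.
#' @return the model, invisibly; errors on any violation.
#' @export
audit_model <- function(model) {
  emb <- lapply(model$branches, .embedding_dim)
  if (model$kind == "combined") {
    fused <- sum(unlist(emb))
    head_in <- model$head[[1]]$n_in
    if (head_in != fused)
      stop("fusion head expects ", head_in, " inputs but streams supply ",
           fused, call. = FALSE)
  }
  if (!is.null(model$head)) {
    last <- model$head[[length(model$head)]]
    if (last$type != "dense" || last$n_out != 2L)
      stop("classification head must end in a 2-unit layer", call. = FALSE)
  }
  invisible(model)
}

#' Build the tabular stream
#'
#' @param spec a [naive_stream_spec()].
#' @param mode `"standalone"` appends the 2-class softmax head;
#'   `"fusion"` exposes the final hidden layer as a 32-dim embedding.
#' @return a `dg_model`.
#' @export
build_naive_stream <- function(spec = naive_stream_spec(),
                               mode = c("standalone", "fusion")) {
  mode <- match.arg(mode)
  layers <- .mlp_layers(spec$input_dim, spec$hidden_dims, spec$dropout)
  head <- if (mode == "standalone")
    list(lay_dense(utils::tail(spec$hidden_dims, 1), 2L)) else NULL
  .new_model("naive", list(naive = layers), head, list(naive = spec))
}

#' Build the grid stream
#'
#' @param spec a [grid_stream_spec()].
#' @param mode `"standalone"` appends a 2-class softmax head;
#'   `"fusion"` exposes the final FC layer as the embedding.
#' @return a `dg_model`.
#' @export
build_grid_stream <- function(spec = grid_stream_spec(),
                              mode = c("standalone", "fusion")) {
  mode <- match.arg(mode)
  layers <- .grid_layers(spec)
  head <- if (mode == "standalone")
    list(lay_dense(utils::tail(spec$fc_dims, 1), 2L)) else NULL
  .new_model("grid", list(grid = layers), head, list(grid = spec))
}

#' Build the fused two-stream classifier
#'
#' Concatenates the tabular and grid stream embeddings (32 + 32 = 64 by
#' default) and refines them through the fusion head to a 2-class
#' softmax.
#'
#' @param naive_spec a [naive_stream_spec()].
#' @param grid_spec a [grid_stream_spec()].
#' @param spec a [combined_spec()].
#' @return a `dg_model`.
#' @export
build_combined <- function(naive_spec = naive_stream_spec(),
                           grid_spec = grid_stream_spec(),
                           spec = combined_spec()) {
  nb <- .mlp_layers(naive_spec$input_dim, naive_spec$hidden_dims,
                    naive_spec$dropout)
  gb <- .grid_layers(grid_spec)
  fused <- utils::tail(naive_spec$hidden_dims, 1) +
    utils::tail(grid_spec$fc_dims, 1)
  head <- list()
  n_in <- fused
  for (j in seq_along(spec$fc_dims)) {
    head <- c(head, list(lay_dense(n_in, spec$fc_dims[j]), lay_relu()))
    if (j == 1 && spec$dropout > 0)
      head <- c(head, list(lay_dropout(spec$dropout)))
    n_in <- spec$fc_dims[j]
  }
  head <- c(head, list(lay_dense(n_in, 2L)))
  .new_model("combined", list(naive = nb, grid = gb), head,
             list(naive = naive_spec, grid = grid_spec, combined = spec))
}

#' Initialize model parameters
#'
#' He-scaled normal initialization of every dense/convolution layer.
#' Called by [train_model()] under its configured seed; exposed so the
#' forward pass can be exercised without training.
#'
#' @param model a `dg_model`.
#' @param seed optional RNG seed set before drawing weights.
#' @return the model with parameters populated.
#' @export
init_params <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model$branches <- lapply(model$branches, init_layer_params)
  if (!is.null(model$head)) model$head <- init_layer_params(model$head)
  model
}

#' Count trainable parameters
#'
#' @param model a `dg_model` (initialized or not).
#' @return total number of weights and biases.
#' @export
count_params <- function(model) {
  one <- function(layers) sum(vapply(layers, function(l) {
    if (is.null(l$n_in)) 0L else l$n_in * l$n_out + l$n_out
  }, integer(1)))
  sum(vapply(model$branches, one, integer(1))) +
    if (is.null(model$head)) 0L else one(model$head)
}

.forward_model <- function(model, x_naive, x_grid, training = FALSE) {
  bc <- list()
  outs <- list()
  for (nm in names(model$branches)) {
    X <- if (nm == "naive") x_naive else x_grid
    if (is.null(X)) stop("model requires '", nm, "' inputs", call. = FALSE)
    fw <- stack_forward(model$branches[[nm]], X, training)
    bc[[nm]] <- fw$caches
    outs[[nm]] <- fw$out
  }
  H <- do.call(cbind, unname(outs))
  if (is.null(model$head))
    return(list(out = H, branch_caches = bc, head_caches = NULL,
                branch_dims = vapply(outs, ncol, integer(1))))
  hw <- stack_forward(model$head, H, training)
  list(out = hw$out, branch_caches = bc, head_caches = hw$caches,
       branch_dims = vapply(outs, ncol, integer(1)))
}

#' Train a classifier on labeled segments
#'
#' Minimizes softmax cross-entropy with Adam. All randomness (weight
#' initialization, shuffling, dropout) flows from `cfg$seed`, so a given
#' seed reproduces the fitted weights exactly.
#'
#' @param model a `dg_model` with a classification head.
#' @param data list with `y` (0/1 integer labels) and, as the model
#'   requires, `x_naive` (n x p feature matrix) and/or `x_grid`
#'   (n x G^2 flattened occupancy grids, x fastest within y).
#' @param cfg a [training_config()].
#' @return the fitted model; `$history` holds the mean training loss per
#'   epoch and `$config` the configuration used.
#' @export
train_model <- function(model, data, cfg = training_config()) {
  if (is.null(model$head))
    stop("fusion-mode embedders have no classification head to train",
         call. = FALSE)
  y <- as.integer(data$y)
  if (length(unique(y)) < 2)
    stop("degenerate training set: only one class present", call. = FALSE)
  n <- length(y)
  set.seed(cfg$seed)
  model <- init_params(model)
  st_branch <- lapply(model$branches, adam_init)
  st_head <- adam_init(model$head)
  t_step <- 0
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      xb_n <- if (!is.null(data$x_naive))
        data$x_naive[idx, , drop = FALSE] else NULL
      xb_g <- if (!is.null(data$x_grid))
        data$x_grid[idx, , drop = FALSE] else NULL
      yb <- y[idx]
      fw <- .forward_model(model, xb_n, xb_g, training = TRUE)
      p <- softmax_rows(fw$out)
      m <- length(yb)
      losses <- c(losses, -mean(log(pmax(p[cbind(seq_len(m), yb + 1L)],
                                         1e-12))))
      Y <- matrix(0, m, 2)
      Y[cbind(seq_len(m), yb + 1L)] <- 1
      dlogits <- (p - Y) / m
      hb <- stack_backward(model$head, fw$head_caches, dlogits)
      t_step <- t_step + 1
      up <- adam_step(model$head, hb$grads, st_head, cfg$learning_rate,
                      t_step)
      model$head <- up$layers
      st_head <- up$state
      off <- 0L
      for (nm in names(model$branches)) {
        d <- fw$branch_dims[[nm]]
        dH <- hb$dX[, (off + 1L):(off + d), drop = FALSE]
        off <- off + d
        bb <- stack_backward(model$branches[[nm]], fw$branch_caches[[nm]],
                             dH)
        upb <- adam_step(model$branches[[nm]], bb$grads, st_branch[[nm]],
                         cfg$learning_rate, t_step)
        model$branches[[nm]] <- upb$layers
        st_branch[[nm]] <- upb$state
      }
    }
    history[epoch] <- mean(losses)
  }
  model$fitted <- TRUE
  model$config <- cfg
  model$history <- history
  model
}

#' Class probabilities from a fitted classifier
#'
#' @param model a fitted `dg_model`.
#' @param data list with `x_naive` and/or `x_grid` as the model requires.
#' @return n x 2 matrix with columns `p_normal`, `p_abnormal`; rows sum
#'   to 1.
#' @export
predict_proba <- function(model, data) {
  if (!isTRUE(model$fitted))
    stop("model has not been trained", call. = FALSE)
  fw <- .forward_model(model, data$x_naive, data$x_grid, training = FALSE)
  p <- softmax_rows(fw$out)
  colnames(p) <- c("p_normal", "p_abnormal")
  p
}

#' Stream embedding from a fusion-mode model
#'
#' @param model a `dg_model` built in fusion mode (no head), with
#'   initialized parameters.
#' @param data list with the stream's inputs.
#' @return n x d embedding matrix.
#' @export
stream_embedding <- function(model, data) {
  fw <- .forward_model(model, data$x_naive, data$x_grid, training = FALSE)
  fw$out
}

#' @export
print.dg_model <- function(x, ...) {
  cat("<dg_model>", x$kind,
      if (is.null(x$head)) "(fusion-mode embedder)" else "(classifier)",
      "\n  parameters:", count_params(x),
      "\n  fitted:", isTRUE(x$fitted), "\n")
  invisible(x)
}
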