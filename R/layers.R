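# Layer constructors and the module convention.
#
# A module is a named list of parameter tensors and/or sub-modules plus
# plain-R configuration, with a class for dispatch through `fwd()`. Parameter
# discovery walks the nesting, so optimizers, counting and checkpointing all
# share one traversal.

#' Forward pass through a module
#' @param mod module object
#' @param x input tensor
#' @param training logical; selects batch-statistics vs running-statistics mode
#' @param ... passed through
#' @return output tensor
#' @export
fwd <- function(mod, x, training = FALSE, ...) UseMethod("fwd")

## ---- constructors ----------------------------------------------------------

nn_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, dil = 1L,
                      bias = TRUE) {
  k <- rep(as.integer(k), length.out = 2L)
  stride <- rep(as.integer(stride), length.out = 2L)
  dil <- rep(as.integer(dil), length.out = 2L)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L * dil # "same" for stride 1
  pad <- rep(as.integer(pad), length.out = 2L)
  sd <- sqrt(2 / (cin * k[1] * k[2]))
  m <- list(
    w = dbh_param(array(stats::rnorm(cout * cin * k[1] * k[2], sd = sd),
                        c(cout, cin, k[1], k[2]))),
    b = if (bias) dbh_param(rep(0, cout)) else NULL,
    stride = stride, pad = pad, dil = dil
  )
  class(m) <- c("nn_conv2d", "dbh_module")
  m
}

#' @export
fwd.nn_conv2d <- function(mod, x, training = FALSE, ...) {
  t_conv2d(x, mod$w, mod$b, stride = mod$stride, pad = mod$pad, dil = mod$dil)
}

nn_bn2d <- function(c, eps = 1e-5, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$rmean <- rep(0, c)
  st$rvar <- rep(1, c)
  m <- list(gamma = dbh_param(rep(1, c)), beta = dbh_param(rep(0, c)),
            state = st, eps = eps, momentum = momentum)
  class(m) <- c("nn_bn2d", "dbh_module")
  m
}

#' @export
fwd.nn_bn2d <- function(mod, x, training = FALSE, ...) {
  t_bn2d(x, mod$gamma, mod$beta, mod$state, training,
         eps = mod$eps, momentum = mod$momentum)
}

# conv -> BN -> optional ReLU, the workhorse unit of the convolutional branch
nn_cbr <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, dil = 1L,
                   relu = TRUE) {
  m <- list(conv = nn_conv2d(cin, cout, k, stride, pad, dil),
            bn = nn_bn2d(cout), relu = relu)
  class(m) <- c("nn_cbr", "dbh_module")
  m
}

#' @export
fwd.nn_cbr <- function(mod, x, training = FALSE, ...) {
  y <- fwd(mod$bn, fwd(mod$conv, x, training), training)
  if (mod$relu) t_relu(y) else y
}

nn_linear <- function(din, dout, bias = TRUE, sd = 0.02) {
  m <- list(w = dbh_param(matrix(stats::rnorm(din * dout, sd = sd), din, dout)),
            b = if (bias) dbh_param(rep(0, dout)) else NULL)
  class(m) <- c("nn_linear", "dbh_module")
  m
}

#' @export
fwd.nn_linear <- function(mod, x, training = FALSE, ...) {
  t_linear(x, mod$w, mod$b)
}

nn_ln <- function(d, eps = 1e-5) {
  m <- list(gamma = dbh_param(rep(1, d)), beta = dbh_param(rep(0, d)), eps = eps)
  class(m) <- c("nn_ln", "dbh_module")
  m
}

#' @export
fwd.nn_ln <- function(mod, x, training = FALSE, ...) {
  t_layernorm(x, mod$gamma, mod$beta, eps = mod$eps)
}

nn_seq <- function(...) {
  m <- list(mods = list(...))
  class(m) <- c("nn_seq", "dbh_module")
  m
}

#' @export
fwd.nn_seq <- function(mod, x, training = FALSE, ...) {
  for (sub in mod$mods) x <- fwd(sub, x, training)
  x
}

## ---- parameter traversal ---------------------------------------------------

#' Collect all trainable parameters of a model
#'
#' @param mod a module (possibly deeply nested)
#' @param prefix name prefix used for the returned names
#' @return named list of parameter tensors; names encode the module path
#' @export
collect_params <- function(mod, prefix = "") {
  out <- list()
  if (is_tensor(mod)) {
    if (mod$requires) out[[prefix]] <- mod
    return(out)
  }
  if (!is.list(mod)) return(out)
  nms <- names(mod)
  for (i in seq_along(mod)) {
    item <- mod[[i]]
    if (is.null(item) || is.environment(item) && !is_tensor(item)) next
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    child <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    out <- c(out, collect_params(item, child))
  }
  out
}

#' Count trainable parameters of a model
#'
#' @param model a module or model built by [build_model()]
#' @return integer count of trainable scalar parameters; the count in millions
#'   (2 decimals) is attached as attribute `"millions"`
#' @export
count_parameters <- function(model) {
  ps <- collect_params(model)
  n <- sum(vapply(ps, function(p) length(p$value), 0))
  attr(n, "millions") <- round(n / 1e6, 2)
  n
}

#' Export model weights as a named list of plain arrays
#' @param model a module
#' @return named list of numeric arrays
#' @export
state_dict <- function(model) {
  lapply(collect_params(model), function(p) p$value)
}

#' Load weights from a named list of arrays into a model
#'
#' Keys are matched by name; shape mismatches and unmatched keys are reported.
#'
#' @param model a module
#' @param state named list of arrays (e.g. from [state_dict()] or a converted
#'   external checkpoint)
#' @param strict error on any mismatch instead of reporting
#' @return invisibly, a list with `loaded`, `missing`, `unexpected`,
#'   `shape_mismatch` key vectors
#' @export
load_state_dict <- function(model, state, strict = FALSE) {
  ps <- collect_params(model)
  loaded <- character(); mism <- character()
  for (nm in names(ps)) {
    if (!nm %in% names(state)) next
    new <- state[[nm]]
    old <- ps[[nm]]$value
    same <- length(new) == length(old) &&
      identical(as.integer(dim(new) %||% length(new)),
                as.integer(dim(old) %||% length(old)))
    if (!same) {
      mism <- c(mism, sprintf("%s: have %s, checkpoint %s", nm,
                              paste(dim(old) %||% length(old), collapse = "x"),
                              paste(dim(new) %||% length(new), collapse = "x")))
      next
    }
    ps[[nm]]$value <- new
    loaded <- c(loaded, nm)
  }
  missing <- setdiff(names(ps), loaded)
  unexpected <- setdiff(names(state), names(ps))
  if (strict && (length(mism) || length(missing) || length(unexpected))) {
    stop("load_state_dict: ", length(mism), " shape mismatches, ",
         length(missing), " missing, ", length(unexpected), " unexpected keys\n",
         paste(utils::head(mism, 10), collapse = "\n"))
  }
  invisible(list(loaded = loaded, missing = missing,
                 unexpected = unexpected, shape_mismatch = mism))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
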