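# Safe evaluation of user-supplied parametric expressions. Only the parameter
# t, numeric literals, basic arithmetic, and a fixed whitelist of functions
# (sin, cos, tan, exp, log, abs, sqrt) plus the constants pi and e are allowed;
# anything else is rejected before evaluation, so no arbitrary code runs.

.fiber_expr_funs <- c("sin", "cos", "tan", "exp", "log", "abs", "sqrt",
                      "+", "-", "*", "/", "^", "(")
.fiber_expr_syms <- c("t", "pi", "e")

check_fiber_expr <- function(expr_text) {
  parsed <- tryCatch(
    parse(text = expr_text, keep.source = FALSE),
    error = function(e) {
      stop_validation(paste0(
        "cannot parse expression '", expr_text, "': ", conditionMessage(e)
      ))
    }
  )
  if (length(parsed) != 1) {
    stop_validation(paste0("expression '", expr_text, "' must be a single expression"))
  }
  walk <- function(node) {
    if (is.numeric(node) || is.integer(node)) return(invisible())
    if (is.name(node)) {
      if (!as.character(node) %in% .fiber_expr_syms) {
        stop_validation(paste0(
          "symbol '", as.character(node), "' is not allowed in expression '",
          expr_text, "' (allowed: t, pi, e)"
        ))
      }
      return(invisible())
    }
    if (is.call(node)) {
      fun <- as.character(node[[1]])
      if (!fun %in% .fiber_expr_funs) {
        stop_validation(paste0(
          "function '", fun, "' is not allowed in expression '", expr_text,
          "' (allowed: ", paste(setdiff(.fiber_expr_funs, "("), collapse = ", "), ")"
        ))
      }
      for (k in seq_along(node)[-1]) walk(node[[k]])
      return(invisible())
    }
    stop_validation(paste0("unsupported token in expression '", expr_text, "'"))
  }
  walk(parsed[[1]])
  parsed[[1]]
}

eval_fiber_expr <- function(expr_text, t) {
  node <- check_fiber_expr(expr_text)
  env <- new.env(parent = baseenv())
  assign("t", t, envir = env)
  assign("pi", pi, envir = env)
  assign("e", exp(1), envir = env)
  val <- eval(node, envir = env)
  if (length(val) == 1) val <- rep(val, length(t))
  if (length(val) != length(t)) {
    stop_validation(paste0("expression '", expr_text, "' did not evaluate pointwise in t"))
  }
  as.numeric(val)
}

#' Generate a fiber from parametric functions of t
#'
#' Samples the four expressions `x(t)`, `y(t)`, `z(t)`, `r(t)` at
#' `n_steps + 1` uniformly spaced values of `t` in `[t_min, t_max]`.
#' Expressions may use `t`, numeric literals, `pi`, `e`, arithmetic, and
#' `sin`, `cos`, `tan`, `exp`, `log`, `abs`, `sqrt`.
#'
#' @param fx,fy,fz,fr Character expressions of `t` for the coordinates and
#'   radius (micrometres).
#' @param t_min,t_max Parameter range, `t_min < t_max`.
#' @param n_steps Number of uniform steps (the fiber gets `n_steps + 1` points).
#' @param fiber,group Identifier and group path for the generated fiber.
#' @return A `fiber_phantom` with one fiber.
#' @examples
#' # a conical helix envelope
#' parametric_fiber("50*sin(t*pi)", "50*cos(t*pi)", "50*t", "-abs(15*t)+15",
#'                  -0.5, 0.5, 100)
#' @export
parametric_fiber <- function(fx, fy, fz, fr, t_min, t_max, n_steps,
                             fiber = "fiber_1", group = "") {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_min >= t_max) {
    stop_validation("t_min must be smaller than t_max")
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1) {
    stop_validation("n_steps must be a positive integer")
  }
  t <- seq(t_min, t_max, length.out = n_steps + 1)
  x <- eval_fiber_expr(fx, t)
  y <- eval_fiber_expr(fy, t)
  z <- eval_fiber_expr(fz, t)
  r <- eval_fiber_expr(fr, t)
  if (any(r < 0)) {
    bad <- t[which(r < 0)[1]]
    stop_validation(paste0(
      "radius expression evaluates negative at t = ", format(bad)
    ))
  }
  fiber_points(x, y, z, r, fiber = fiber, group = group)
}
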