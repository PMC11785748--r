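#' Strategy labels
#'
#' The four behavioural types of the model, in canonical order: cooperators
#' (C) contribute a fraction `c` of their endowment to the public good;
#' punishers (P) and rewarders (R) contribute as well and additionally pay a
#' tax `pi_t` towards a group-level institution; defectors (D) contribute
#' nothing.
#'
#' @format Character vector of length 4.
#' @export
CRD_STRATEGIES <- c("C", "P", "R", "D")

#' Model variants
#'
#' `"electoral"` is the full four-strategy model in which the nature of each
#' group's institution (reward vs. punishment) is decided by majority vote
#' among its P and R members. `"reward"` and `"punish"` restrict the dynamics
#' to the faces of the strategy simplex with no punishers (resp. no
#' rewarders), recovering reward-only and punishment-only institutional
#' designs. `"none"` is the bare collective risk dilemma with cooperators and
#' defectors only.
#'
#' @format Character vector of length 4.
#' @export
CRD_VARIANTS <- c("electoral", "reward", "punish", "none")

#' Active strategy set of a model variant
#'
#' @param variant One of [CRD_VARIANTS].
#' @return Character vector of the strategies that may appear in populations
#'   and groups under `variant` (a subset of [CRD_STRATEGIES], in canonical
#'   order).
#' @examples
#' active_strategies("electoral")
#' active_strategies("none")
#' @export
active_strategies <- function(variant) {
  variant <- match.arg(variant, CRD_VARIANTS)
  switch(variant,
    electoral = c("C", "P", "R", "D"),
    reward    = c("C", "R", "D"),
    punish    = c("C", "P", "D"),
    none      = c("C", "D")
  )
}

check_scalar <- function(x, key, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", key),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("parameter '%s' must be an integer (got %s)", key,
                 format(x)), call. = FALSE)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop(sprintf(
      "parameter '%s' = %s violates bound %s%s, %s]", key, format(x),
      if (strict_lower) "(" else "[", format(lower), format(upper)),
      call. = FALSE)
  }
  invisible(x)
}

#' Model parameter bundle
#'
#' Single source of truth for one model configuration: population and group
#' structure, the collective-risk-dilemma stakes, the institutional design,
#' and the evolutionary dynamics settings.
#'
#' @param Z Population size (integer, `>= N`).
#' @param N Group size (integer, `>= 2`).
#' @param n_pg Public-goods threshold: minimum number of contributors
#'   (C + P + R) a group needs for guaranteed success (integer in `1..N`).
#' @param n_I Institution-formation threshold: minimum number of taxed
#'   strategists (P + R) needed to create the group institution
#'   (integer in `1..N`).
#' @param b Endowment each individual starts with (`> 0`).
#' @param c Fraction of the endowment contributed by pro-social strategies
#'   (in `[0, 1]`).
#' @param r Risk: probability that every group member loses the endowment
#'   when the contribution threshold is missed (in `[0, 1]`).
#' @param delta Institution multiplier: return factor on the collected taxes
#'   (`>= 1`).
#' @param pi_t Institution tax paid by P and R on top of their contribution
#'   (`>= 0`).
#' @param mu Mutation probability per update step (in `[0, 1]`).
#' @param beta Selection strength (inverse temperature) of the pairwise
#'   comparison rule (`>= 0`).
#' @param variant Model variant, one of [CRD_VARIANTS].
#' @return An object of class `crd_params` (a validated named list).
#' @examples
#' p <- crd_params(Z = 20, N = 4, n_pg = 3, n_I = 2)
#' p$S  # number of active strategies
#' @export
crd_params <- function(Z, N = 8L, n_pg = 6L, n_I = 2L, b = 1, c = 0.1,
                       r = 0.5, delta = 2, pi_t = 0.03, mu = 1 / Z,
                       beta = 2, variant = "electoral") {
  variant <- match.arg(variant, CRD_VARIANTS)
  check_scalar(N, "N", lower = 2, integer = TRUE)
  check_scalar(Z, "Z", lower = N, integer = TRUE)
  check_scalar(n_pg, "n_pg", lower = 1, upper = N, integer = TRUE)
  check_scalar(n_I, "n_I", lower = 1, upper = N, integer = TRUE)
  check_scalar(b, "b", lower = 0, strict_lower = TRUE)
  check_scalar(c, "c", lower = 0, upper = 1)
  check_scalar(r, "r", lower = 0, upper = 1)
  check_scalar(delta, "delta", lower = 1)
  check_scalar(pi_t, "pi_t", lower = 0)
  check_scalar(mu, "mu", lower = 0, upper = 1)
  check_scalar(beta, "beta", lower = 0)
  act <- active_strategies(variant)
  p <- list(
    Z = as.integer(Z), N = as.integer(N), n_pg = as.integer(n_pg),
    n_I = as.integer(n_I), b = b, c = c, r = r, delta = delta,
    pi_t = pi_t, mu = mu, beta = beta, variant = variant,
    active = act, S = length(act)
  )
  class(p) <- "crd_params"
  p
}

#' Modify a parameter bundle
#'
#' Returns a revalidated copy of `p` with the named fields replaced; used
#' internally for risk sweeps (`set_params(p, r = 0.7)`).
#'
#' @param p A `crd_params` object.
#' @param ... Named fields of [crd_params] to replace.
#' @return A new `crd_params` object.
#' @export
set_params <- function(p, ...) {
  stopifnot(inherits(p, "crd_params"))
  repl <- list(...)
  keep <- setdiff(names(formals(crd_params)), names(repl))
  args <- c(p[intersect(keep, names(p))], repl)
  do.call(crd_params, args)
}

#' Named parameter presets
#'
#' Two ready-made study configurations used throughout the documentation and
#' the acceptance suite:
#' \describe{
#'   \item{`"attractor"`}{Z = 70, mu = 1/70, beta = 5, N = 8, n_pg = 6,
#'     n_I = 2, b = 1, c = 0.1, delta = 2, pi_t = 0.03, r = 0.8 — the setting
#'     in which the stationary distribution exhibits an interior cooperative
#'     attractor alongside a near-all-defector attractor.}
#'   \item{`"sweep"`}{Z = 140, mu = 1/140, beta = 2, same group parameters,
#'     r free — the setting for risk curves and critical-risk comparisons
#'     across the four variants.}
#' }
#'
#' @param name `"attractor"` or `"sweep"`.
#' @param ... Overrides passed on to [set_params] (e.g. `variant`, `r`).
#' @return A `crd_params` object.
#' @examples
#' crd_preset("attractor")
#' crd_preset("sweep", variant = "none", r = 0.75)
#' @export
crd_preset <- function(name = c("attractor", "sweep"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    attractor = crd_params(Z = 70L, N = 8L, n_pg = 6L, n_I = 2L, b = 1,
                           c = 0.1, r = 0.8, delta = 2, pi_t = 0.03,
                           mu = 1 / 70, beta = 5, variant = "electoral"),
    sweep = crd_params(Z = 140L, N = 8L, n_pg = 6L, n_I = 2L, b = 1,
                       c = 0.1, r = 0.5, delta = 2, pi_t = 0.03,
                       mu = 1 / 140, beta = 2, variant = "electoral")
  )
  if (...length() > 0L) p <- set_params(p, ...) else p
}

#' @export
print.crd_params <- function(x, ...) {
  cat(sprintf(
    "<crd_params> variant=%s (S=%d: %s)\n  Z=%d N=%d n_pg=%d n_I=%d\n",
    x$variant, x$S, paste(x$active, collapse = ","),
    x$Z, x$N, x$n_pg, x$n_I))
  cat(sprintf("  b=%g c=%g r=%g delta=%g pi_t=%g mu=%g beta=%g\n",
              x$b, x$c, x$r, x$delta, x$pi_t, x$mu, x$beta))
  invisible(x)
}

#' Canonical string and hash of a parameter bundle
#'
#' The canonical string lists every field at full precision in fixed order;
#' the hash is its MD5 digest. Both are embedded in exported artifacts so a
#' result can always be traced back to its exact configuration.
#'
#' @param p A `crd_params` object.
#' @return `params_string`: a single character string; `params_hash`: its
#'   32-character MD5 digest.
#' @export
params_string <- function(p) {
  stopifnot(inherits(p, "crd_params"))
  num <- function(x) sprintf("%.17g", x)
  paste0(
    "variant=", p$variant, ";Z=", p$Z, ";N=", p$N, ";n_pg=", p$n_pg,
    ";n_I=", p$n_I, ";b=", num(p$b), ";c=", num(p$c), ";r=", num(p$r),
    ";delta=", num(p$delta), ";pi_t=", num(p$pi_t), ";mu=", num(p$mu),
    ";beta=", num(p$beta)
  )
}

#' @rdname params_string
#' @export
params_hash <- function(p) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(params_string(p), f)
  unname(tools::md5sum(f))
}
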