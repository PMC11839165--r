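#' Build a reaction for a stochastic reaction network
#'
#' A reaction is defined by its state-change (stoichiometry) vector and its
#' propensity. Propensities can be given in one of two forms:
#' \itemize{
#'   \item a *rate spec* (`rate_spec()`), a restricted product form
#'     `k / div * F1(x) * F2(x)` with affine factors, which the compiled
#'     Gillespie core can evaluate (fast path); or
#'   \item an arbitrary R function `propensity(state, t)` returning a
#'     non-negative rate in 1/s (general path, used by the reference R
#'     engine).
#' }
#'
#' @param name Reaction label (used in diagnostics).
#' @param delta Named numeric vector of species changes, e.g.
#'   `c(n1 = +1, free = -1)`.
#' @param rate_spec A [rate_spec()] object, or `NULL`.
#' @param propensity A function `(state, t) -> rate`, or `NULL`.
#' @return An object of class `reaction`.
#' @export
reaction <- function(name, delta, rate_spec = NULL, propensity = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(delta)) || any(!nzchar(names(delta))))
    stop("`delta` must be a named vector of species changes")
  if (is.null(rate_spec) && is.null(propensity))
    stop("reaction '", name, "' needs a rate_spec or a propensity function")
  structure(list(name = name, delta = delta, rate_spec = rate_spec,
                 propensity = propensity),
            class = "reaction")
}

#' Affine-factor propensity specification
#'
#' Encodes a propensity of the form `k / div * F1 * F2` where each factor
#' `F` is affine in at most two species: `F = coef . x[species] + const`.
#' Mass-action examples: a unimolecular step is `k * x[A]`
#' (`f1 = affine("A")`); a pool-scaled bimolecular step is
#' `k * x[A] * x[B] / (c*Vc)` (`div = c*Vc`, two factors); an affine
#' size-feedback factor such as `(Sa + Sb + 1)` is
#' `affine(c("Sa","Sb"), const = 1)`.
#'
#' @param k Rate constant (units such that the propensity is 1/s after
#'   division by `div`).
#' @param f1,f2 Factors built with [affine()]; `f2 = NULL` means no second
#'   factor.
#' @param div Divisor, typically 1 or `c * Vc`.
#' @return An object of class `rate_spec`.
#' @export
rate_spec <- function(k, f1, f2 = NULL, div = 1) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0, div > 0)
  structure(list(k = k, f1 = f1, f2 = f2, div = div), class = "rate_spec")
}

#' @param species Character vector (0, 1 or 2 species names).
#' @param coef Coefficients, recycled to `length(species)`.
#' @param const Constant term.
#' @rdname rate_spec
#' @export
affine <- function(species = character(), coef = 1, const = 0) {
  species <- as.character(species)
  if (length(species) > 2L) stop("affine factors support at most two species")
  coef <- rep_len(coef, length(species))
  structure(list(species = species, coef = coef, const = const),
            class = "affine_factor")
}

#' Assemble a reaction network
#'
#' The container shared by the stochastic and deterministic engines: an
#' ordered species list, an initial count vector, the reactions, and any
#' conserved sums (linear combinations of species that the dynamics must
#' preserve, e.g. total subunits free + incorporated).
#'
#' @param species Character vector of species labels.
#' @param initial_state Named numeric vector of initial counts (non-negative
#'   integers; checked).
#' @param reactions List of [reaction()] objects.
#' @param conserved Optional list of `list(coef = <named numeric>,
#'   total = <numeric>)`; each must hold at `initial_state`.
#' @param meta Optional named list of metadata (parameters, unit convention,
#'   derived-series definitions) carried into trajectories.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, initial_state, reactions,
                             conserved = list(), meta = list()) {
  stopifnot(is.character(species), length(species) >= 1L)
  if (!setequal(names(initial_state), species))
    stop("initial_state names must match species")
  initial_state <- initial_state[species]
  if (any(initial_state < 0) || any(initial_state != round(initial_state)))
    stop("initial counts must be non-negative integers")
  for (r in reactions) {
    if (!inherits(r, "reaction")) stop("reactions must be reaction() objects")
    unknown <- setdiff(names(r$delta), species)
    if (length(unknown))
      stop("reaction '", r$name, "' references unknown species: ",
           paste(unknown, collapse = ", "))
  }
  for (cs in conserved) {
    val <- sum(cs$coef * initial_state[names(cs$coef)])
    if (abs(val - cs$total) > 1e-9)
      stop("conserved sum violated at initial state (", val, " != ",
           cs$total, ")")
  }
  structure(list(species = species, initial_state = initial_state,
                 reactions = reactions, conserved = conserved, meta = meta),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %d species, %d reactions>\n",
              length(x$species), length(x$reactions)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

# --- internal: encode a network for the compiled core ----------------------

encode_factor_row <- function(f, species) {
  if (is.null(f)) return(c(-2, 0, -1, 0, 1))   # absent factor => 1
  idx <- match(f$species, species) - 1L        # 0-based
  row <- c(-1, 0, -1, 0, f$const)
  if (length(idx) >= 1L) { row[1] <- idx[1]; row[2] <- f$coef[1] }
  if (length(idx) >= 2L) { row[3] <- idx[2]; row[4] <- f$coef[2] }
  row
}

encode_network <- function(network) {
  sp <- network$species
  R <- length(network$reactions)
  S <- length(sp)
  delta <- matrix(0L, R, S, dimnames = list(NULL, sp))
  k <- numeric(R); div <- numeric(R)
  f1 <- matrix(0, R, 5); f2 <- matrix(0, R, 5)
  nm <- character(R)
  for (j in seq_len(R)) {
    r <- network$reactions[[j]]
    if (is.null(r$rate_spec)) return(NULL)     # fall back to the R engine
    delta[j, names(r$delta)] <- as.integer(r$delta)
    k[j] <- r$rate_spec$k
    div[j] <- r$rate_spec$div
    f1[j, ] <- encode_factor_row(r$rate_spec$f1, sp)
    f2[j, ] <- encode_factor_row(r$rate_spec$f2, sp)
    nm[j] <- r$name
  }
  list(delta = delta, k = k, div = div, f1 = f1, f2 = f2, names = nm)
}

# evaluate all propensities at a (possibly continuous) state; used by the
# deterministic twin and the reference R engine
eval_propensities <- function(network, state, t = 0) {
  vapply(network$reactions, function(r) {
    if (!is.null(r$rate_spec)) {
      rs <- r$rate_spec
      fval <- function(f) {
        if (is.null(f)) return(1)
        s <- if (length(f$species)) sum(f$coef * state[f$species]) else 0
        s + f$const
      }
      rs$k / rs$div * fval(rs$f1) * fval(rs$f2)
    } else {
      r$propensity(state, t)
    }
  }, numeric(1))
}

# stoichiometry matrix (reactions x species)
delta_matrix <- function(network) {
  sp <- network$species
  out <- matrix(0, length(network$reactions), length(sp),
                dimnames = list(vapply(network$reactions, `[[`, "", "name"), sp))
  for (j in seq_along(network$reactions)) {
    d <- network$reactions[[j]]$delta
    out[j, names(d)] <- d
  }
  out
}

#' Check the conserved sums of a network along a trajectory
#'
#' @param network A [reaction_network()].
#' @param trajectory A [trajectory] produced from that network.
#' @param tol Absolute tolerance (0 for exact stochastic paths).
#' @return `TRUE` invisibly if all sums hold; otherwise stops.
#' @export
check_conserved <- function(network, trajectory, tol = 0) {
  for (cs in network$conserved) {
    vals <- as.matrix(trajectory$states[, names(cs$coef), drop = FALSE]) %*% cs$coef
    bad <- which(abs(vals - cs$total) > tol + 1e-9)
    if (length(bad))
      stop("conserved sum violated at time ", trajectory$times[bad[1]],
           " (", vals[bad[1]], " != ", cs$total, ")")
  }
  invisible(TRUE)
}
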