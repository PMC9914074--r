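#' Basic probability assignment over the excretion frame
#'
#' A mass function assigns unit belief to the four focal sets of the frame:
#' A = \{u\} (urine), B = \{s\} (stool), C = \{u, s\} (both) and D = \{n\}
#' (no detection). Masses must be non-negative and sum to one (within 1e-9).
#'
#' @param urine,stool,both,none masses in \[0, 1\]. Alternatively pass a
#'   single numeric vector of length 4 (A, B, C, D order) as `urine`.
#' @return an object of class `mass_function`: a named numeric vector in
#'   canonical A, B, C, D order.
#' @examples
#' mass_function(0.25, 0.25, 0.25, 0.25)
#' mass_function(c(0.2, 0.3, 0.4, 0.1))
#' @export
mass_function <- function(urine, stool = NULL, both = NULL, none = NULL) {
  m <- if (is.null(stool) && length(urine) == 4L) as.numeric(urine)
       else c(urine, stool, both, none)
  if (length(m) != 4L) stop("a mass function needs exactly 4 masses", call. = FALSE)
  names(m) <- event_labels()
  class(m) <- "mass_function"
  validate_mass(m)
  m
}

#' @rdname mass_function
#' @param m object to validate.
#' @param tol tolerance on the unit-sum constraint.
#' @export
validate_mass <- function(m, tol = 1e-9) {
  v <- unclass(m)
  if (!is.numeric(v) || length(v) != 4L || anyNA(v)) {
    stop("mass function must be 4 finite numerics", call. = FALSE)
  }
  if (any(v < -tol)) stop("masses must be non-negative", call. = FALSE)
  if (abs(sum(v) - 1) > max(tol, 1e-9)) {
    stop(sprintf("masses must sum to 1 (got %.12f)", sum(v)), call. = FALSE)
  }
  invisible(m)
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  cat("<mass function>  ",
      paste(sprintf("m(%s)=%.*f", event_codes(), digits, unclass(x)),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Floor and renormalize a mass function
#'
#' Raises every mass to at least `eps` and renormalizes. Used throughout the
#' detection pipeline before combination so that no pair of mass functions is
#' ever in total conflict (K = 0).
#'
#' @param m a [mass_function()].
#' @param eps floor applied to each mass before renormalization.
#' @return a valid `mass_function`.
#' @export
floor_mass <- function(m, eps = 1e-4) {
  v <- pmax(unclass(m), eps)
  mass_function(v / sum(v))
}

#' Conflict (normalization) coefficient of Dempster's rule
#'
#' K is the total mass that two bodies of evidence assign to pairs of focal
#' sets with non-empty intersection; equivalently one minus the mass lost to
#' empty intersections. On this frame the non-empty pairs are (A,A), (A,C),
#' (C,A), (B,B), (B,C), (C,B), (C,C) and (D,D). K = 0 means the two mass
#' functions are in total conflict and cannot be combined.
#'
#' @param m1,m2 [mass_function()] objects.
#' @return the scalar K in \[0, 1\].
#' @examples
#' m <- mass_function(0.25, 0.25, 0.25, 0.25)
#' conflict_coefficient(m, m) # 0.5
#' @export
conflict_coefficient <- function(m1, m2) {
  validate_mass(m1); validate_mass(m2)
  a1 <- m1[[1]]; b1 <- m1[[2]]; c1 <- m1[[3]]; d1 <- m1[[4]]
  a2 <- m2[[1]]; b2 <- m2[[2]]; c2 <- m2[[3]]; d2 <- m2[[4]]
  a1 * a2 + a1 * c2 + c1 * a2 +
    b1 * b2 + b1 * c2 + c1 * b2 +
    c1 * c2 + d1 * d2
}

#' Dempster's rule of combination on the excretion frame
#'
#' Combines two bodies of evidence by the orthogonal sum: masses of focal-set
#' pairs are multiplied, products are accumulated on the intersection of the
#' pair, and the result is renormalized by the conflict coefficient K. Since
#' C = A union B, event A receives the (A,A), (A,C) and (C,A) products, B the
#' symmetric ones, while C and D only receive their own diagonal products.
#'
#' @param m1,m2 [mass_function()] objects.
#' @return the fused `mass_function`.
#' @seealso [ds_fuse()] for n-ary fusion, [conflict_coefficient()].
#' @examples
#' m <- mass_function(0.25, 0.25, 0.25, 0.25)
#' ds_combine(m, m) # (0.375, 0.375, 0.125, 0.125)
#' @export
ds_combine <- function(m1, m2) {
  K <- conflict_coefficient(m1, m2)
  if (K <= 0) {
    stop("total conflict: the two mass functions cannot be combined (K = 0)",
         call. = FALSE)
  }
  a1 <- m1[[1]]; b1 <- m1[[2]]; c1 <- m1[[3]]; d1 <- m1[[4]]
  a2 <- m2[[1]]; b2 <- m2[[2]]; c2 <- m2[[3]]; d2 <- m2[[4]]
  mass_function(c(a1 * a2 + a1 * c2 + c1 * a2,
                  b1 * b2 + b1 * c2 + c1 * b2,
                  c1 * c2,
                  d1 * d2) / K)
}

#' Fuse an ordered collection of mass functions
#'
#' Left fold of [ds_combine()]. Dempster's rule is associative and
#' commutative, so the association order does not change the result.
#'
#' @param masses a non-empty list of [mass_function()] objects.
#' @return the fused `mass_function`.
#' @export
ds_fuse <- function(masses) {
  if (!is.list(masses) || length(masses) < 1L) {
    stop("ds_fuse() needs a non-empty list of mass functions", call. = FALSE)
  }
  Reduce(ds_combine, masses)
}

#' Decide the event from a fused mass function
#'
#' Returns the event with the highest mass. Ties are broken in severity
#' order both > stool > urine > none, preferring the decision that triggers
#' the most complete cleaning action.
#'
#' @param m a [mass_function()].
#' @return one of `event_labels()`.
#' @examples
#' ds_decide(mass_function(0.1, 0.2, 0.6, 0.1)) # "both"
#' ds_decide(mass_function(0.4, 0.4, 0.1, 0.1)) # "stool" (tie order)
#' @export
ds_decide <- function(m) {
  validate_mass(m)
  idx <- .severity_idx()
  severity_order()[which.max(unclass(m)[idx])]
}

#' Serialize mass functions to and from data frames
#'
#' Mass functions travel as 4-column rows `m_A, m_B, m_C, m_D`.
#'
#' @param x a `mass_function` or a list of them.
#' @param ... unused.
#' @return a data frame with columns `m_A`, `m_B`, `m_C`, `m_D`.
#' @export
as.data.frame.mass_function <- function(x, ...) {
  d <- as.data.frame(as.list(stats::setNames(unclass(x),
                                             paste0("m_", event_codes()))))
  rownames(d) <- NULL
  d
}

#' @rdname as.data.frame.mass_function
#' @param d a data frame with columns `m_A`..`m_D` (one row per mass).
#' @return `masses_from_df()` returns a list of `mass_function` objects.
#' @export
masses_from_df <- function(d) {
  cols <- paste0("m_", event_codes())
  if (!all(cols %in% names(d))) {
    stop("expected columns ", paste(cols, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(d)), function(i) mass_function(as.numeric(d[i, cols])))
}
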