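# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a residue key from chain and residue id
#'
#' Residue identity throughout the package is `(chain, resid, insertion-code)`;
#' keys are rendered as `"chain:residicode"` (icode omitted when blank).
#' Generic labels (GPCRdb / CGN) are aliases, never primary keys.
#'
#' @param chain chain identifier(s)
#' @param resid integer residue number(s) (author numbering, as deposited)
#' @param icode insertion code(s), default blank
#' @return character vector of residue keys
#' @export
res_key <- function(chain, resid, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resid, icode)
}

#' Wrap angles to the canonical torsion interval
#'
#' Maps degrees into `[-180, 180)`; +180 maps to -180 so every angle has a
#' single representation (needed for deterministic circular binning).
#'
#' @param deg numeric angles in degrees
#' @return wrapped angles in degrees
#' @export
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w >= 180] <- -180
  w
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Restore the caller's RNG state on exit; seeds a local stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Euclidean distance matrix between two n x 3 coordinate blocks.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
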