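#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames predict pnorm dnorm cor sd
#' @importFrom utils head tail
NULL

# 3-letter <-> 1-letter amino acid tables
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- setNames(AA3, AA1)

aa_three_to_one <- function(x) {
  out <- unname(AA1[x])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(x) {
  out <- unname(AA3_FROM_1[x])
  out[is.na(out)] <- "UNK"
  out
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-10) {
    stop("degenerate geometry: zero-length vector cannot be normalized",
         call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic draws that do not disturb the caller's RNG stream.
local_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  rnorm(n)
}

# Stable 31-bit string hash (polynomial rolling hash); pure R, no deps.
hash31 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (cd in codes) h <- (h * 131 + cd) %% 2147483647
  as.integer(h)
}

#' Random rigid motion (rotation + translation)
#'
#' Draws a uniformly random 3x3 rotation matrix (via QR of a Gaussian
#' matrix, sign-corrected to det +1) and a translation vector. Used to
#' exercise the rigid-motion invariance of the geometric features.
#'
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param translation_sd Standard deviation (Angstrom) of the Gaussian
#'   translation components.
#' @return List with elements `R` (3x3 rotation, det +1) and `t`
#'   (length-3 translation).
#' @export
random_rigid_motion <- function(seed, translation_sd = 10) {
  x <- local_rnorm(seed, 12)
  m <- matrix(x[1:9], 3, 3)
  qr_ <- qr(m)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = x[10:12] * translation_sd)
}
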