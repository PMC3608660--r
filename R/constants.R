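# Physical constants and embedded model matrices.
#
# Residue masses are monoisotopic, computed from standard atomic masses
# (CODATA/IUPAC); monoisotopic arithmetic is required for the 0.98402 Da
# deamidation shift to be distinguishable from isotope spacing.

.PROTON <- 1.00727646688
.WATER  <- 18.0105646837

# Model-order amino-acid alphabet (Dayhoff/PAML convention).
.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.RESIDUE_MASS <- c(
  A =  71.03711379, R = 156.10111102, N = 114.04292744, D = 115.02694302,
  C = 103.00918448, Q = 128.05857751, E = 129.04259309, G =  57.02146372,
  H = 137.05891186, I = 113.08406398, L = 113.08406398, K = 128.09496302,
  M = 131.04048509, F = 147.06841391, P =  97.05276385, S =  87.03202841,
  T = 101.04767847, W = 186.07931295, Y = 163.06332853, V =  99.06841392)

#' Monoisotopic residue mass table
#'
#' Returns the monoisotopic masses (Da) of the 20 standard amino-acid
#' residues (i.e. amino acids minus water, as incorporated in a chain).
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' residueMasses()[["G"]]  # 57.02146
residueMasses <- function() .RESIDUE_MASS

#' Shipped variable-modification set
#'
#' The variable modifications used throughout the pipeline: hydroxylation /
#' oxidation (+15.99491 Da on P, K, M; hydroxyproline is represented as P plus
#' this modification, never as a 21st letter), deamidation (+0.98402 Da on
#' N, Q), and N-terminal pyroglutamate formation from Q (-17.02655 Da) or E
#' (-18.01056 Da).
#'
#' @return A data.frame with columns \code{name}, \code{delta} (monoisotopic
#'   Da), \code{residues} (allowed residues, collapsed string) and
#'   \code{nterm} (logical; restricted to the peptide N-terminus).
#' @export
collagenMods <- function() {
  data.frame(
    name     = c("ox", "deam", "pyroQ", "pyroE"),
    delta    = c(15.99491461956, 0.98401558269, -17.02654910101, -18.01056468370),
    residues = c("PKM", "NQ", "Q", "E"),
    nterm    = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# Dayhoff exchangeabilities, lower triangle in .AA_ORDER (canonical PAML
# dayhoff.dat scaling), and equilibrium frequencies (renormalised to sum 1).
.DAYHOFF_S <- c(
    27,   98,  120,   36,   89,  198,  240,   23,   65,   41,   26,   72,
    18,  250,  409,  371,    0,   24,  208,   32,    0,   23,  246,    1,
     9,  240,   64,   15,  464,   90,   14,  103,  154,   26,  201,    8,
    24,  905,    0,  103,  148,  139,  535,   77,   34,  318,    1,   14,
    42,  495,  229,   23,   95,   15,    0,  134, 1153,  125,   86,   24,
     0,   71,    0,    0,   13,   95,   66,    0,    0,   18,    0,    0,
    11,   28,   44,    0,    0,    0,    0,   19,  161,   16,    0,   96,
    49,  716,   28,  606,   18,   73,  153,  114,    0,  153,   56,   53,
     0,    0,   35,   81,   43,   61,   11,   83,   30,    0,   51,   79,
    34,    0,   22,   37,   10,    0,    7,   27,   17,   15,   34,  234,
    30,    0,    0,   54,    7,   44,   26,    0,   48,   94,   35,   22,
    27,  127,   44,  257,   46,  336,  196,   12,   24,  192,    0,   37,
   889,   18,  527,  157,   32,   17,   33,   46,   28,  175,  243,    0,
    33,   96,  136,    0,   13,   10,   92,   17,   62,  104,    0,    0,
   258,   11,   46,   13,   76,  698,   12,  245,   78,    0,    0,   48,
   550,   75,   34,   30,    0,   42,  157,   61,    0,   28)

.DAYHOFF_PI <- c(0.087127, 0.040904, 0.040432, 0.046872, 0.033474, 0.038255,
                 0.049530, 0.088612, 0.033618, 0.036886, 0.085357, 0.080482,
                 0.014753, 0.039772, 0.050680, 0.069577, 0.058542, 0.010494,
                 0.029916, 0.064718)

#' Dayhoff equilibrium amino-acid frequencies
#'
#' @return Named numeric vector (model order A,R,N,D,...), summing to 1.
#' @export
dayhoffFrequencies <- function() {
  pi <- .DAYHOFF_PI / sum(.DAYHOFF_PI)
  names(pi) <- .AA_ORDER
  pi
}

#' Dayhoff instantaneous rate matrix
#'
#' Builds the reversible 20x20 rate matrix Q from the embedded Dayhoff
#' exchangeabilities and equilibrium frequencies, scaled so the expected rate
#' at equilibrium is one substitution per site (branch lengths are then in
#' expected substitutions/site).
#'
#' @return 20x20 numeric matrix with rows summing to zero.
#' @export
dayhoffRateMatrix <- function() {
  s <- matrix(0, 20, 20, dimnames = list(.AA_ORDER, .AA_ORDER))
  s[lower.tri(s)] <- .DAYHOFF_S
  s <- s + t(s)
  pi <- dayhoffFrequencies()
  q <- s * rep(pi, each = 20)      # q_ij = s_ij * pi_j
  diag(q) <- -rowSums(q)
  q / sum(pi * -diag(q))           # mean rate 1
}

# Eigendecomposition of Q, cached; reversibility makes B = D^{1/2} Q D^{-1/2}
# symmetric so the decomposition is numerically exact.
.dayhoffEigen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      q <- dayhoffRateMatrix()
      pi <- dayhoffFrequencies()
      d <- sqrt(pi)
      b <- diag(d) %*% q %*% diag(1 / d)
      e <- eigen((b + t(b)) / 2, symmetric = TRUE)
      cache <<- list(values = e$values,
                     right = diag(1 / d) %*% e$vectors,
                     left  = t(e$vectors) %*% diag(d))
    }
    cache
  }
})

#' Dayhoff transition probability matrix
#'
#' Computes P(t) = exp(Qt) for the embedded Dayhoff model via the cached
#' spectral decomposition of the reversible rate matrix.
#'
#' @param t Branch length in expected substitutions/site (scalar, >= 0).
#' @return 20x20 row-stochastic matrix.
#' @export
dayhoffTransition <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  e <- .dayhoffEigen()
  p <- e$right %*% (exp(e$values * t) * e$left)
  p[p < 0] <- 0
  dimnames(p) <- list(.AA_ORDER, .AA_ORDER)
  p
}
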