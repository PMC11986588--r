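# Local alignment and its significance statistics.

# ungapped Karlin-Altschul K values for common nucleotide schemes
# (match, mismatch) -> K; the default +1/-2 scheme is tabulated, other
# schemes fall back to the H/lambda approximation (flagged).
.ka_k_table <- list("1/-2" = 0.621)

#' Alignment scoring scheme
#'
#' Match/mismatch scores with affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`), plus the Karlin-Altschul
#' parameters lambda and K used to convert raw scores into bit scores
#' and E-values. When `lambda`/`k_param` are not supplied they are
#' solved from the scores and background frequencies by
#' [karlin_altschul_params()].
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap_open,gap_extend negative gap penalties.
#' @param background per-base frequencies (A, C, G, T), summing to 1.
#' @param lambda,k_param optional explicit Karlin-Altschul parameters.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           lambda = NULL, k_param = NULL) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            abs(sum(background) - 1) < 1e-8)
  sch <- list(match = as.integer(match), mismatch = as.integer(mismatch),
              gap_open = as.integer(gap_open),
              gap_extend = as.integer(gap_extend),
              background = background)
  if (is.null(lambda) || is.null(k_param)) {
    ka <- karlin_altschul_params(match, mismatch, background)
    sch$lambda <- if (is.null(lambda)) ka$lambda else lambda
    sch$k_param <- if (is.null(k_param)) ka$k_param else k_param
    sch$k_approximate <- ka$approximate
  } else {
    sch$lambda <- lambda; sch$k_param <- k_param
    sch$k_approximate <- FALSE
  }
  stopifnot(sch$lambda > 0, sch$k_param > 0)
  class(sch) <- "scoring_scheme"
  sch
}

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' lambda is the unique positive root of
#' sum_ij p_i p_j exp(lambda * s_ij) = 1, solved to |residual| < 1e-9.
#' K comes from a built-in table for the default +1/-2 uniform scheme;
#' for other schemes the H/lambda approximation is used and flagged.
#'
#' @param match,mismatch scores.
#' @param background per-base frequencies.
#' @return list(lambda, k_param, residual, approximate).
#' @export
karlin_altschul_params <- function(match = 1L, mismatch = -2L,
                                   background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25)) {
  p_match <- sum(background^2)
  p_mis <- 1 - p_match
  escore <- p_match * match + p_mis * mismatch
  if (escore >= 0)
    stop("scheme not in log-odds regime: expected score per aligned pair ",
         "must be negative")
  if (match <= 0) stop("scheme not in log-odds regime: max score must be > 0")
  f <- function(l) p_match * exp(l * match) + p_mis * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  # refine by bisection until the residual contract holds
  lo <- lambda - 1e-6; hi2 <- lambda + 1e-6
  while (abs(f(lambda)) >= 1e-9) {
    if (f(lambda) > 0) hi2 <- lambda else lo <- lambda
    lambda <- (lo + hi2) / 2
  }
  key <- paste0(match, "/", mismatch)
  uniform <- all(abs(background - 0.25) < 1e-9)
  if (uniform && !is.null(.ka_k_table[[key]])) {
    k_param <- .ka_k_table[[key]]; approximate <- FALSE
  } else {
    # relative entropy H = lambda * E[S exp(lambda S)] (nats/pair)
    H <- lambda * (p_match * match * exp(lambda * match) +
                   p_mis * mismatch * exp(lambda * mismatch))
    k_param <- max(H / lambda, 1e-3) * exp(-lambda)
    approximate <- TRUE
  }
  list(lambda = lambda, k_param = k_param, residual = f(lambda),
       approximate = approximate)
}

#' Best local alignment under affine gaps
#'
#' Smith-Waterman over `{A,C,G,T,N}` (N always scores as a mismatch).
#' Deterministic: among equal-scoring alignments the one whose end has
#' the smallest subject position, then the smallest query position, is
#' returned, with a diagonal-first traceback.
#'
#' @param query,subject DNA strings.
#' @param scheme a [scoring_scheme()].
#' @return list(raw_score, query_interval, subject_interval (0-based
#'   half-open), n_columns, identity).
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme()) {
  r <- sw_align_cpp(toupper(query), toupper(subject), scheme$match,
                    scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                    traceback = TRUE)
  list(raw_score = r$score,
       query_interval = c(r$q_start, r$q_end),
       subject_interval = c(r$s_start, r$s_end),
       n_columns = r$n_columns,
       identity = if (r$n_columns > 0) r$n_matches / r$n_columns else NA_real_)
}

#' Bit score and E-value of a raw alignment score
#'
#' `bit = (lambda * S - ln K) / ln 2`; `E = m * n * 2^(-bit)`.
#'
#' @param raw_score integer raw score.
#' @param m query length (the TE sequence).
#' @param n subject search-space length (total exon-set length).
#' @param scheme a [scoring_scheme()].
#' @return list(bit_score, evalue).
#' @export
hit_statistics <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  bit <- (scheme$lambda * raw_score - log(scheme$k_param)) / log(2)
  list(bit_score = bit, evalue = m * n * 2^(-bit))
}
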