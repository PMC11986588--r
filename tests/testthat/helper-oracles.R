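# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (combinatorial enumeration), structurally different
# from the implementations they check.

# --- local alignment oracle -------------------------------------------
# Enumerates every possible set of aligned columns: choose k matched
# index pairs (increasing in both sequences); gaps are the index jumps
# between consecutive columns, each run costing gap_open + len *
# gap_extend. Returns the maximum score over all column sets (empty
# alignment scores 0).
sw_oracle <- function(query, subject, scheme = scoring_scheme()) {
  qv <- strsplit(toupper(query), "")[[1]]
  sv <- strsplit(toupper(subject), "")[[1]]
  m <- length(qv); n <- length(sv)
  col_score <- function(a, b) {
    if (a %in% c("A", "C", "G", "T") && a == b) scheme$match
    else scheme$mismatch
  }
  gap_cost <- function(len) {
    if (len == 0) 0 else scheme$gap_open + len * scheme$gap_extend
  }
  best <- 0
  for (k in seq_len(min(m, n))) {
    qi_sets <- utils::combn(m, k, simplify = FALSE)
    si_sets <- utils::combn(n, k, simplify = FALSE)
    for (qi in qi_sets) for (si in si_sets) {
      sc <- 0
      for (t in seq_len(k)) sc <- sc + col_score(qv[qi[t]], sv[si[t]])
      if (k > 1) {
        for (t in 2:k) {
          sc <- sc + gap_cost(qi[t] - qi[t - 1] - 1)
          sc <- sc + gap_cost(si[t] - si[t - 1] - 1)
        }
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# --- NG86 oracle ------------------------------------------------------
# Explicit enumeration: sites by trying all 9 single-base changes of
# each codon; differences by walking every permutation of the differing
# positions, dropping walks that pass through a stop codon.
ng86_oracle <- function(cds_a, cds_b) {
  gc <- Biostrings::GENETIC_CODE
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(toupper(cds_a)); cb <- split3(toupper(cds_b))
  syn_sites <- function(cod) {
    v <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (bb in setdiff(c("A", "C", "G", "T"), v[p])) {
      w <- v; w[p] <- bb
      if (gc[[paste(w, collapse = "")]] != "*" &&
          gc[[paste(w, collapse = "")]] == gc[[cod]]) s <- s + 1 / 3
    }
    s
  }
  S <- (sum(vapply(ca, syn_sites, 0)) + sum(vapply(cb, syn_sites, 0))) / 2
  perms_of <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    va <- strsplit(ca[i], "")[[1]]; vb <- strsplit(cb[i], "")[[1]]
    pos <- which(va != vb)
    if (!length(pos)) next
    walks <- list()
    for (ord in perms_of(pos)) {
      cur <- va; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- vb[p]
        a1 <- gc[[paste(cur, collapse = "")]]
        a2 <- gc[[paste(nxt, collapse = "")]]
        if (a2 == "*") { ok <- FALSE; break }
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) walks[[length(walks) + 1]] <- c(sd, nd)
    }
    if (!length(walks)) {
      for (ord in perms_of(pos)) {
        cur <- va; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur; nxt[p] <- vb[p]
          a1 <- gc[[paste(cur, collapse = "")]]
          a2 <- gc[[paste(nxt, collapse = "")]]
          if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        walks[[length(walks) + 1]] <- c(sd, nd)
      }
    }
    w <- do.call(rbind, walks)
    Sd <- Sd + mean(w[, 1]); Nd <- Nd + mean(w[, 2])
  }
  list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd)
}

# --- Wilcoxon enumeration oracle --------------------------------------
# Two-sided p from full enumeration of all C(n, n_a) group assignments
# of the pooled sample (no ties assumed): p = min(1, 2 * min(P(W <= w),
# P(W >= w))) with W the Mann-Whitney U of group A.
wilcoxon_oracle <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_of <- function(idx) {
    ga <- pool[idx]; gb <- pool[-idx]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  w_obs <- u_of(seq_len(na))
  ws <- vapply(utils::combn(n, na, simplify = FALSE), u_of, 0)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# random stop-free CDS and a mutated copy (uniform substitutions,
# stop-avoiding), used for Ka/Ks checks
random_codons <- function(n, avoid = c("TAA", "TAG", "TGA")) {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  paste(sample(setdiff(all3, avoid), n, replace = TRUE), collapse = "")
}

mutate_uniform_cds <- function(s, rate) {
  gc <- Biostrings::GENETIC_CODE
  v <- strsplit(s, "")[[1]]
  for (i in seq_along(v)) {
    if (runif(1) < rate) {
      old <- v[i]
      cand <- setdiff(c("A", "C", "G", "T"), old)
      v[i] <- sample(cand, 1)
      cod_i <- (i - 1) %/% 3
      cod <- paste(v[(3 * cod_i + 1):(3 * cod_i + 3)], collapse = "")
      if (gc[[cod]] == "*") v[i] <- old
    }
  }
  paste(v, collapse = "")
}
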