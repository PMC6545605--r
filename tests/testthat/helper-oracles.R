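# Independent brute-force oracles used to validate the package's
# implementations.  They deliberately share no code with R/.

# --- hypergeometric upper tail by direct log-space summation ---------------
oracle_hyper_tail <- function(N, a, b, k) {
  if (k == 0) return(1)
  kk <- k:min(a, b)
  sum(exp(lchoose(a, kk) + lchoose(N - a, b - kk) - lchoose(N, b)))
}

# --- NG86 by enumeration ----------------------------------------------------
oracle_translate <- local({
  has_seqinr <- requireNamespace("seqinr", quietly = TRUE)
  function(codon) {
    if (has_seqinr) {
      seqinr::translate(unlist(strsplit(codon, "")))
    } else {
      unname(Biostrings::GENETIC_CODE[codon])
    }
  }
})

oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  ch <- unlist(strsplit(codon, ""))
  s <- 0
  for (pos in 1:3) {
    for (b in bases[bases != ch[pos]]) {
      m <- ch; m[pos] <- b
      mc <- paste(m, collapse = "")
      if (oracle_translate(mc) != "*" &&
          oracle_translate(mc) == oracle_translate(codon)) {
        s <- s + 1 / 3
      }
    }
  }
  c(s = s, n = 3 - s)
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  if (length(v) == 2L) return(list(v, rev(v)))
  list(v[c(1, 2, 3)], v[c(1, 3, 2)], v[c(2, 1, 3)],
       v[c(2, 3, 1)], v[c(3, 1, 2)], v[c(3, 2, 1)])
}

oracle_diffs <- function(ca, cb) {
  a <- unlist(strsplit(ca, "")); b <- unlist(strsplit(cb, ""))
  dp <- which(a != b)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  paths <- lapply(oracle_perms(dp), function(ord) {
    cur <- a; sd <- 0; nd <- 0; stopped <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      f <- oracle_translate(paste(cur, collapse = ""))
      t <- oracle_translate(paste(nxt, collapse = ""))
      if (t == "*") stopped <- TRUE
      if (f != "*" && t != "*" && f == t) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, stopped = stopped)
  })
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

oracle_ng86 <- function(sa, sb) {
  n <- nchar(sa) %/% 3
  st <- 3 * seq_len(n) - 2
  ca <- substring(sa, st, st + 2)
  cb <- substring(sb, st, st + 2)
  S <- N <- Sd <- Nd <- 0
  for (i in seq_len(n)) {
    sia <- oracle_sites(ca[i]); sib <- oracle_sites(cb[i])
    S <- S + (sia[["s"]] + sib[["s"]]) / 2
    N <- N + (sia[["n"]] + sib[["n"]]) / 2
    d <- oracle_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  jc <- function(p) if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# --- exact multinomial tail of the Pearson statistic (2 categories) --------
oracle_exact_chisq_tail <- function(n, p, stat) {
  # enumerate all outcomes (j, n - j) of a 2-category multinomial
  total <- 0
  E <- n * p
  for (j in 0:n) {
    s <- (j - E[1])^2 / E[1] + ((n - j) - E[2])^2 / E[2]
    if (s >= stat) total <- total + dbinom(j, n, p[1])
  }
  total
}
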