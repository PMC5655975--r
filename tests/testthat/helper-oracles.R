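# Independent brute-force oracles. Everything here is written from the rule
# definitions with plain loops, deliberately sharing no code with R/.

# Rule-by-rule PPT validity check (independent of is_valid_ppt).
oracle_valid_ppt <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_py <- function(x) x == "C" || x == "T"
  if (!is_py(ch[1]) || !is_py(ch[n])) return(FALSE)
  if (n < 9 && sum(ch == "T") < 5) return(FALSE)

  # mark G's inside T(GT)n stretches: leftmost, non-overlapping, greedy
  exempt <- rep(FALSE, n)
  i <- 1
  while (i <= n - 2) {
    if (ch[i] == "T" && ch[i + 1] == "G" && ch[i + 2] == "T") {
      j <- i
      while (j + 2 <= n && ch[j + 1] == "G" && ch[j + 2] == "T") {
        exempt[j + 1] <- TRUE
        j <- j + 2
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }

  # purine segments, their lengths and flanking pyrimidine runs
  i <- 1
  while (i <= n) {
    if (!is_py(ch[i])) {
      j <- i
      while (j < n && !is_py(ch[j + 1])) j <- j + 1
      l <- j - i + 1
      if (l > 2) return(FALSE)
      seg_exempt <- l == 1 && ch[i] == "G" && exempt[i]
      if (!seg_exempt) {
        left <- 0
        k <- i - 1
        while (k >= 1 && is_py(ch[k])) {
          left <- left + 1
          k <- k - 1
        }
        right <- 0
        k <- j + 1
        while (k <= n && is_py(ch[k])) {
          right <- right + 1
          k <- k + 1
        }
        if (left < l || right < l || left + right < 4 * l) return(FALSE)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  TRUE
}

# Brute-force PPT search: every substring, filtered by is_valid_ppt, kept if
# not extendable by one base (within the window) into a still-valid string,
# selected by 3'-most end then 3'-most start. Returns c(start, end) in
# 1-based window coordinates, or NULL.
oracle_find_ppt_window <- function(w) {
  n <- nchar(w)
  best <- NULL
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      s <- substr(w, i, j)
      if (!is_valid_ppt(s)) next
      if (i > 1 && is_valid_ppt(substr(w, i - 1, j))) next
      if (j < n && is_valid_ppt(substr(w, i, j + 1))) next
      if (is.null(best) || j > best[2] || (j == best[2] && i > best[1])) {
        best <- c(i, j)
      }
    }
  }
  best
}

# First-principles re-implementation of the prediction pipeline for one
# intron: fresh AG scan, brute-force PPT, suffix run, direct S* formula.
oracle_predict <- function(seq, f, energy, P, Q, L = 9) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  at <- function(p) ch[n + p + 1]

  # defining AG: first AG with its A at or 5' of -(12+1)
  a <- NA
  for (p in -13:(-n)) {
    if (at(p) == "A" && p + 1 <= -1 && at(p + 1) == "G") {
      a <- p
      break
    }
  }
  agez_start <- if (is.na(a)) -n else max(a - L, -n)

  # brute-force PPT in the AGEZ core
  core_start <- if (is.na(a)) -n else a
  w <- substr(seq, n + core_start + 1, n)
  hit <- oracle_find_ppt_window(w)
  short_end <- -1
  if (!is.null(hit)) {
    ppt_start <- core_start + hit[1] - 1
    ppt_end <- core_start + hit[2] - 1
    r <- ppt_end
    while (r - 1 >= ppt_start && at(r - 1) %in% c("C", "T")) r <- r - 1
    short_end <- r - 1
  }
  if (short_end < agez_start) return(NULL)

  # scan every in-zone heptamer, S* from first principles
  best <- NULL
  for (p in agez_start:short_end) {
    if (p - 5 < -n || p + 1 > -1) next
    hept <- paste(ch[(n + p - 5 + 1):(n + p + 1 + 1)], collapse = "")
    if (grepl("N", hept)) next
    hch <- strsplit(hept, "")[[1]]
    s <- 0
    for (i in 1:7) s <- s + log2(f[hch[i], i])
    term <- 0
    if (sum(P) > 0) {
      for (j in 1:3) {
        k <- j + 4
        hx <- chartr("T", "U", paste(hch[-k], collapse = ""))
        term <- term + P[j] * energy[[hx]] * f[hch[k], k]^Q[j]
      }
      term <- term / sum(P)
    }
    sc <- s - term
    if (is.null(best) || sc > best$score ||
        (sc == best$score && p > best$branch_pos)) {
      best <- list(branch_pos = p, heptamer = hept, score = sc)
    }
  }
  best
}

# Random DNA with a pyrimidine bias (so valid tracts actually occur).
random_seq <- function(n, py_bias = 0.62) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - py_bias) / 2, py_bias / 2,
                        (1 - py_bias) / 2, py_bias / 2)),
        collapse = "")
}

nn_table <- function() build_energy_table("nn")
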