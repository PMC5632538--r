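# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (loops, enumeration, full DP in
# plain R) and share no code path with the package internals they check.

# --- Benjamini-Hochberg step-up, literal definition ------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(k) m * p[o[k]] / k)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# --- complete-linkage agglomeration by O(n^3) enumeration -------------------
# returns the sequence of merge heights and merged member sets
oracle_complete_linkage <- function(x) {
  # x: samples in columns
  clusters <- as.list(colnames(x))
  heights <- numeric()
  members <- character()
  d <- as.matrix(dist(t(x)))
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best - 1e-12) { best <- h; bi <- i; bj <- j }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights <- c(heights, best)
    members <- c(members, paste(merged, collapse = ","))
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  data.frame(height = heights, members = members, stringsAsFactors = FALSE)
}

# --- upper-tail hypergeometric by exhaustive draw enumeration ---------------
oracle_hyper_tail <- function(k, K, N, n) {
  # P[overlap >= k] when drawing n from N containing K successes
  total <- choose(N, n)
  sum(sapply(k:min(K, n), function(i) choose(K, i) * choose(N - K, n - i))) /
    total
}

# --- longest ORF by explicit 3-frame scan -----------------------------------
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (frame in 0:2) {
    i <- 1L + frame
    while (i + 2L <= n) {
      if (substr(seq, i, i + 2) == "ATG") {
        j <- i
        while (j + 2L <= n) {
          cod <- substr(seq, j, j + 2)
          if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, j + 3L - i)
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  best
}

# --- seed-weighted local alignment scan, full DP in plain R -----------------
# mirrors the documented scanner conventions exactly but is an independent
# implementation (matrix DP with explicit state tracking, no masking tricks
# shared with the C++ code)
oracle_scan <- function(region, mirna, match = 5, wobble = 2, mismatch = -3,
                        gap_open = -8, gap_extend = -2, seed_lo = 2,
                        seed_hi = 8, seed_mult = 2, score_min = 140) {
  pair_class <- function(m, r) {
    if ((m == "A" && r == "T") || (m == "U" && r == "A") ||
        (m == "G" && r == "C") || (m == "C" && r == "G")) return(1L)
    if ((m == "G" && r == "T") || (m == "U" && r == "G")) return(2L)
    0L
  }
  pair_type <- function(m, r) {
    cl <- pair_class(m, r)
    if (cl == 2L) return(3L)
    if (cl == 1L) return(if (m %in% c("G", "C")) 1L else 2L)
    0L
  }
  L <- nchar(region); M <- nchar(mirna)
  rg <- strsplit(region, "")[[1]]
  q <- rev(strsplit(mirna, "")[[1]])
  w <- ifelse((M - seq_len(M) + 1) >= seed_lo & (M - seq_len(M) + 1) <= seed_hi,
              seed_mult, 1)
  NEG <- -1e18
  masked <- rep(FALSE, L)
  sites <- list()
  repeat {
    H <- matrix(0, L + 1, M + 1); E <- matrix(NEG, L + 1, M + 1)
    Fm <- matrix(NEG, L + 1, M + 1)
    pH <- matrix(0L, L + 1, M + 1); pE <- matrix(0L, L + 1, M + 1)
    pF <- matrix(0L, L + 1, M + 1)
    for (i in 2:(L + 1)) {
      if (masked[i - 1]) next  # row stays 0 / NEG
      for (j in 2:(M + 1)) {
        pc <- pair_class(q[j - 1], rg[i - 1])
        s <- (if (pc == 1L) match else if (pc == 2L) wobble else mismatch) *
          w[j - 1]
        eo <- H[i, j - 1] + gap_open; ee <- E[i, j - 1] + gap_extend
        E[i, j] <- max(eo, ee); pE[i, j] <- if (eo >= ee) 1L else 2L
        fo <- H[i - 1, j] + gap_open; fe <- Fm[i - 1, j] + gap_extend
        Fm[i, j] <- max(fo, fe); pF[i, j] <- if (fo >= fe) 1L else 2L
        diag <- H[i - 1, j - 1] + s
        best <- 0; ptr <- 0L
        if (diag >= best) { best <- diag; ptr <- 1L }
        if (E[i, j] > best) { best <- E[i, j]; ptr <- 2L }
        if (Fm[i, j] > best) { best <- Fm[i, j]; ptr <- 3L }
        H[i, j] <- best; pH[i, j] <- ptr
      }
    }
    best <- score_min; bi <- -1L; bj <- -1L
    for (i in 2:(L + 1)) for (j in 2:(M + 1))
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    if (bi < 0) break
    amir <- apair <- areg <- character()
    i <- bi; j <- bj; state <- 0L
    repeat {
      if (state == 0L) {
        ptr <- pH[i, j]
        if (ptr == 0L) break
        if (ptr == 1L) {
          pc <- pair_class(q[j - 1], rg[i - 1])
          amir <- c(q[j - 1], amir)
          apair <- c(if (pc == 1L) "|" else if (pc == 2L) ":" else " ", apair)
          areg <- c(rg[i - 1], areg)
          i <- i - 1L; j <- j - 1L
        } else state <- ptr
      } else if (state == 2L) {
        ptr <- pE[i, j]
        amir <- c(q[j - 1], amir); apair <- c(" ", apair); areg <- c("-", areg)
        j <- j - 1L
        if (ptr == 1L) state <- 0L
      } else {
        ptr <- pF[i, j]
        amir <- c("-", amir); apair <- c(" ", apair)
        areg <- c(rg[i - 1], areg)
        i <- i - 1L
        if (ptr == 1L) state <- 0L
      }
    }
    start_i <- i - 1L; end_i <- bi - 1L
    energy <- 0; prev <- 0L
    for (k in seq_along(amir)) {
      t <- if (amir[k] == "-" || areg[k] == "-") 0L
           else pair_type(amir[k], areg[k])
      if (t > 0L && prev > 0L) {
        energy <- energy + if (t == 3L || prev == 3L) -1.0
          else if (t == 1L && prev == 1L) -3.3
          else if (t == 2L && prev == 2L) -1.1 else -2.1
      }
      prev <- t
    }
    sites[[length(sites) + 1L]] <- data.frame(
      target_start = start_i, target_end = end_i, align_score = best,
      energy = energy, align_mirna = paste(amir, collapse = ""),
      align_pairs = paste(apair, collapse = ""),
      align_region = paste(areg, collapse = ""), stringsAsFactors = FALSE)
    masked[(start_i + 1L):end_i] <- TRUE
  }
  if (!length(sites))
    return(data.frame(target_start = integer(), target_end = integer(),
                      align_score = numeric(), energy = numeric(),
                      align_mirna = character(), align_pairs = character(),
                      align_region = character(), stringsAsFactors = FALSE))
  do.call(rbind, sites)
}

# --- misc fixture builders ---------------------------------------------------
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

make_expr <- function(values, groups = NULL, kind = "counts") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(groups))
    groups <- setNames(rep(c("A", "B"), length.out = ncol(values)),
                       colnames(values))
  expression_matrix(values, groups, kind)
}
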