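# Independent brute-force oracles, deliberately naive implementations.

# Patterning delta by direct window enumeration on substrings.
brute_delta <- function(seq, xs, ys, windows = c(5, 6)) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  fx_tot <- mean(ch %in% xs)
  fy_tot <- mean(ch %in% ys)
  sigma_bar <- (fx_tot - fy_tot)^2 / (fx_tot + fy_tot)
  mean(sapply(windows, function(g) {
    sig <- sapply(1:(n - g + 1), function(i) {
      win <- ch[i:(i + g - 1)]
      fx <- mean(win %in% xs)
      fy <- mean(win %in% ys)
      if (fx + fy == 0) 0 else (fx - fy)^2 / (fx + fy)
    })
    mean((sig - sigma_bar)^2)
  }))
}

# Charge profile by direct window enumeration.
brute_charge_profile <- function(seq, window, pos = c("K", "R"), neg = c("D", "E")) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  w <- sapply(1:(n - window + 1), function(i) {
    win <- ch[i:(i + window - 1)]
    mean(win %in% pos) - mean(win %in% neg)
  })
  sapply(1:n, function(r) {
    idx <- intersect(1:(n - window + 1), (r - window + 1):r)
    mean(w[idx])
  })
}

# Window epsilon by direct pair enumeration.
brute_epsilon <- function(win_a, win_b, w) {
  a <- strsplit(win_a, "")[[1]]
  b <- strsplit(win_b, "")[[1]]
  vals <- c(outer(a, b, Vectorize(function(i, j) w[i, j])))
  mean(vals)
}

# All distinct arrangements of a residue multiset (small n only).
all_arrangements <- function(residues) {
  n <- length(residues)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- v[-i]
      out <- c(out, lapply(perms(rest), function(p) c(v[i], p)))
    }
    out
  }
  unique(vapply(perms(residues), paste, character(1), collapse = ""))
}
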