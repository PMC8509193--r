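# Independent pure-R oracles for the stochastic core.
#
# enumerate_pairings() computes the EXACT outcome distribution of the
# sequential end-matching process by brute force: it averages over all visit
# orders (each with probability 1/n!) and expands every categorical draw
# recursively.  It shares no code with the C++ implementation.

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

pairing_key <- function(junc, free) {
  if (nrow(junc)) {
    junc <- t(apply(junc, 1L, sort))
    junc <- junc[order(junc[, 1], junc[, 2]), , drop = FALSE]
  }
  paste(paste(junc[, 1], junc[, 2], sep = "-", collapse = ","),
        paste(sort(free), collapse = ","), sep = "|")
}

enumerate_pairings <- function(pos, cl, r0, c_free) {
  n <- nrow(pos)
  W <- exp(-as.matrix(dist(pos)) / r0)
  diag(W) <- 0
  dimnames(W) <- NULL
  sib <- outer(cl, cl, "==")
  acc <- new.env(parent = emptyenv())
  add <- function(key, p) {
    assign(key, (if (exists(key, acc)) get(key, acc) else 0) + p, acc)
  }
  recurse <- function(ord, k, state, junc, prob) {
    while (k <= n && state[ord[k]] != 0L) k <- k + 1L
    if (k > n) {
      add(pairing_key(junc, which(state == 2L)), prob)
      return(invisible())
    }
    i <- ord[k]
    cand <- which(state == 0L & !sib[i, ])
    wts <- W[i, cand]
    tot <- sum(wts) + c_free
    if (length(cand) == 0L || tot <= 0) {
      st <- state
      st[i] <- 2L
      recurse(ord, k + 1L, st, junc, prob)
      return(invisible())
    }
    if (c_free > 0) {
      st <- state
      st[i] <- 2L
      recurse(ord, k + 1L, st, junc, prob * c_free / tot)
    }
    for (m in seq_along(cand)) {
      st <- state
      st[i] <- 1L
      st[cand[m]] <- 1L
      recurse(ord, k + 1L, st, rbind(junc, c(i, cand[m])),
              prob * wts[m] / tot)
    }
  }
  perms <- all_perms(n)
  for (p in perms)
    recurse(as.integer(p), 1L, integer(n), matrix(0L, 0L, 2L),
            1 / length(perms))
  probs <- unlist(as.list(acc))
  stopifnot(abs(sum(probs) - 1) < 1e-10)
  probs
}

# exact tally distribution: enumerate pairings, classify each with the
# package classifier, aggregate probabilities per tally signature
enumerate_tallies <- function(lesions, r0, c_free, visibility = 3,
                              karyotype = human_karyotype()) {
  fr <- fragments_from_lesions(lesions, karyotype)
  e <- fr$ends
  pr <- enumerate_pairings(cbind(e$x, e$y, e$z), e$cl, r0, c_free)
  out <- new.env(parent = emptyenv())
  for (key in names(pr)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    junc <- if (nzchar(parts[1])) {
      do.call(rbind, lapply(strsplit(parts[1], ",")[[1]], function(s)
        as.integer(strsplit(s, "-")[[1]])))
    } else matrix(0L, 0L, 2L)
    free <- if (length(parts) > 1L && nzchar(parts[2]))
      as.integer(strsplit(parts[2], ",")[[1]]) else integer(0)
    p <- structure(list(junctions = junc, free = free), class = "pairing")
    tal <- classify(p, fr, visibility)
    tkey <- paste(tal, collapse = "/")
    assign(tkey, (if (exists(tkey, out)) get(tkey, out) else 0) + pr[[key]],
           out)
  }
  unlist(as.list(out))
}

# simulated pairing/tally frequencies over n_rep runs of the package core
simulate_pairing_freqs <- function(lesions, kernel, n_rep,
                                   visibility = 3,
                                   karyotype = human_karyotype()) {
  fr <- fragments_from_lesions(lesions, karyotype)
  e <- fr$ends
  pair_keys <- character(n_rep)
  tally_keys <- character(n_rep)
  for (r in seq_len(n_rep)) {
    p <- rejoin(fr, kernel)
    pair_keys[r] <- pairing_key(p$junctions, p$free)
    tally_keys[r] <- paste(classify(p, fr, visibility), collapse = "/")
  }
  list(pairings = table(pair_keys) / n_rep,
       tallies = table(tally_keys) / n_rep)
}

# |observed frequency - p| <= 3 * binomial sigma (+ tiny slack for p ~ 0)
expect_freq_match <- function(freqs, probs, n) {
  keys <- union(names(freqs), names(probs))
  for (k in keys) {
    obs <- if (k %in% names(freqs)) as.numeric(freqs[[k]]) else 0
    p <- if (k %in% names(probs)) as.numeric(probs[[k]]) else 0
    tol <- 3 * sqrt(p * (1 - p) / n) + 3 / n
    expect_lt(abs(obs - p), max(tol, 1e-12),
              label = sprintf("freq mismatch for outcome %s: obs %.5f vs p %.5f",
                              k, obs, p))
  }
}

# lesions at fixed spatial positions on distinct chromosomes, coordinates
# left of each centromere
fixed_lesions <- function(pos, chrom = seq_len(nrow(pos)),
                          karyotype = human_karyotype()) {
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], chrom = chrom,
             coord_mbp = karyotype$centromere_mbp[chrom] / 2)
}

# compose the R-level per-operation pipeline for one cell (used to
# cross-check the fused C++ simulator)
sim_cell_r <- function(field, cl_yield, dose, nucleus, kernel,
                       visibility = 3) {
  les <- if (field$category == "photon") {
    place_photon_cls(dose, cl_yield, nucleus)
  } else {
    tr <- sample_tracks(dose, field$let, nucleus)
    if (nrow(tr) == 0L) {
      fixed_lesions(matrix(numeric(0), 0, 3), integer(0))
    } else {
      do.call(rbind, lapply(seq_len(nrow(tr)), function(i)
        place_ion_cls(tr[i, ], cl_yield, nucleus)))
    }
  }
  fr <- fragments_from_lesions(les, nucleus$karyotype)
  classify(rejoin(fr, kernel), fr, visibility)
}
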