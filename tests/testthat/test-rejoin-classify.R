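# Sequential end-matching and aberration classification.

test_that("kernel basics: P(0) = 1, strictly decreasing, P(r0) = 1/e", {
  k <- rejoining_kernel(0.8, 0.1)
  expect_equal(kernel_prob(k, 0), 1)
  expect_equal(kernel_prob(k, 0.8), exp(-1), tolerance = 1e-12)
  r <- seq(0, 5, by = 0.1)
  expect_true(all(diff(kernel_prob(k, r)) < 0))
  expect_error(rejoining_kernel(0), "r0")
  expect_error(rejoining_kernel(0.8, -1), "c_free")
})

test_that("two eligible ends pair with probability 1 when c_free = 0", {
  les <- fixed_lesions(rbind(c(0, 0, 0), c(2, 0, 0)), chrom = c(1L, 3L))
  fr <- fragments_from_lesions(les)
  # keep only one end per lesion eligible: with both ends of each CL present
  # (4 ends), pairs always form between non-siblings; check via rejoin
  set.seed(1)
  for (i in 1:50) {
    p <- rejoin(fr, rejoining_kernel(0.8, 0))
    expect_equal(nrow(p$junctions), 2L)
    expect_equal(length(p$free), 0L)
    sib <- matrix(fr$ends$cl[as.vector(p$junctions)], ncol = 2)
    expect_true(all(sib[, 1] != sib[, 2]))
  }
})

test_that("sibling ends never pair: lone CL stays free regardless of c_free", {
  les <- fixed_lesions(rbind(c(0, 0, 0)), chrom = 1L)
  fr <- fragments_from_lesions(les)
  set.seed(2)
  for (cf in c(0, 0.1, 10)) {
    p <- rejoin(fr, rejoining_kernel(0.8, cf))
    expect_equal(nrow(p$junctions), 0L)
    expect_equal(sort(p$free), c(1L, 2L))
  }
})

test_that("pairing partitions the free ends and forbids restitution", {
  nuc <- build_nucleus(3.0)
  kern <- rejoining_kernel(0.8, 0.1)
  set.seed(3)
  for (rep in 1:300) {
    les <- place_photon_cls(2, 8, nuc)
    fr <- fragments_from_lesions(les, nuc$karyotype)
    p <- rejoin(fr, kern)
    used <- c(as.vector(p$junctions), p$free)
    expect_equal(sort(used), seq_len(nrow(fr$ends)))
    if (nrow(p$junctions)) {
      cls <- matrix(fr$ends$cl[as.vector(p$junctions)], ncol = 2)
      expect_true(all(cls[, 1] != cls[, 2]))
    }
  }
})

test_that("classify identifies dicentrics, rings and deletions", {
  k <- human_karyotype()
  # empty pairing on intact chromosomes: all zero
  fr0 <- fragments_from_lesions(fixed_lesions(matrix(numeric(0), 0, 3),
                                              integer(0)), k)
  t0 <- classify(structure(list(junctions = matrix(0L, 0, 2),
                                free = integer(0)), class = "pairing"), fr0)
  expect_equal(unname(unclass(t0)), c(0L, 0L, 0L, 0L))

  # one CL on chr1 and one on chr2 (ends 1,2 and 3,4); join the two centric
  # ends, leave acentric ends free -> 1 dicentric
  les <- data.frame(x = c(0, 0.5), y = 0, z = 0, chrom = c(1L, 3L),
                    coord_mbp = c(60, 40))
  fr <- fragments_from_lesions(les, k)
  e <- fr$ends
  centric_of <- fr$fragments$centric[e$fragment]
  cen_ends <- e$end_id[centric_of]
  acen_ends <- e$end_id[!centric_of]
  p <- structure(list(junctions = matrix(cen_ends, 1, 2), free = acen_ends),
                 class = "pairing")
  tal <- classify(p, fr)
  expect_equal(tal[["dicentrics"]], 1L)
  expect_equal(tal[["centric_rings"]], 0L)
  # the two acentric pieces (60 and ~55 Mbp) are visible deletions
  expect_equal(tal[["deletions"]], 2L)
  expect_equal(tal[["dicentrics_plus_rings"]], 1L)

  # two CLs on one chromosome, centric fragment's ends joined -> centric ring
  les2 <- data.frame(x = c(0, 0.2), y = 0, z = 0, chrom = 1L,
                     coord_mbp = c(60, 200))
  fr2 <- fragments_from_lesions(les2, k)
  cen_frag <- fr2$fragments$id[fr2$fragments$centric &
                                 fr2$fragments$chrom == 1L]
  ring_ends <- fr2$ends$end_id[fr2$ends$fragment == cen_frag]
  others <- setdiff(fr2$ends$end_id, ring_ends)
  p2 <- structure(list(junctions = matrix(ring_ends, 1, 2), free = others),
                  class = "pairing")
  tal2 <- classify(p2, fr2)
  expect_equal(tal2[["centric_rings"]], 1L)
  expect_equal(tal2[["dicentrics"]], 0L)
  expect_equal(tal2[["dicentrics_plus_rings"]], 1L)

  # deletion visibility threshold: sub-threshold acentric piece not counted
  les3 <- data.frame(x = 0, y = 0, z = 0, chrom = 1L,
                     coord_mbp = k$length_mbp[1] - 1)  # 1 Mbp terminal piece
  fr3 <- fragments_from_lesions(les3, k)
  p3 <- structure(list(junctions = matrix(0L, 0, 2),
                       free = fr3$ends$end_id), class = "pairing")
  expect_equal(classify(p3, fr3, visibility_mbp = 3)[["deletions"]], 0L)
  expect_equal(classify(p3, fr3, visibility_mbp = 0.5)[["deletions"]], 1L)

  # element with 3 centromeres counts as 2 equivalent dicentrics
  les4 <- data.frame(x = c(0, 0.1, 0.2), y = 0, z = 0,
                     chrom = c(1L, 3L, 5L), coord_mbp = c(60, 40, 40))
  fr4 <- fragments_from_lesions(les4, k)
  e4 <- fr4$ends
  cen4 <- e4$end_id[fr4$fragments$centric[e4$fragment]]  # 3 centric ends
  # chain: cen1-cen2 via one junction; the centric fragment of chr2 has only
  # one free end, so link cen2's sibling-free... build tricentric by joining
  # centric end of chr1 to centric end of chr3, and centric end of chr3's
  # other... single-cut fragments have one free end each; a 3-centromere
  # chain needs the middle piece to carry 2 free ends: cut chr3 twice.
  les5 <- data.frame(x = c(0, 0.1, 0.2, 0.3), y = 0, z = 0,
                     chrom = c(1L, 5L, 5L, 9L),
                     coord_mbp = c(60, 40, 100, 30))
  fr5 <- fragments_from_lesions(les5, k)
  f5 <- fr5$fragments
  e5 <- fr5$ends
  mid <- f5$id[f5$chrom == 5L & f5$centric]           # centric, two ends
  end_chr1 <- e5$end_id[f5$centric[e5$fragment] &
                          f5$chrom[e5$fragment] == 1L]
  end_chr9 <- e5$end_id[f5$centric[e5$fragment] &
                          f5$chrom[e5$fragment] == 9L]
  mids <- e5$end_id[e5$fragment == mid]
  p5 <- structure(list(junctions = rbind(c(end_chr1, mids[1]),
                                         c(mids[2], end_chr9)),
                       free = setdiff(e5$end_id,
                                      c(end_chr1, end_chr9, mids))),
                  class = "pairing")
  expect_equal(classify(p5, fr5)[["dicentrics"]], 2L)
})

test_that("fused C++ simulator agrees with the composed R-level pipeline", {
  nuc <- build_nucleus(3.0)
  kern <- rejoining_kernel(0.8, 0.1)
  fld <- radiation_field("heavy", 60)
  n_rep <- 400L
  set.seed(60)
  r_tallies <- t(vapply(seq_len(n_rep), function(i)
    as.integer(sim_cell_r(fld, 0.2, 2, nuc, kern)), integer(4)))
  sim <- simulate_dose_response(fld, 0.2, 2, n_cells = 4000, seed = 61)
  m_r <- mean(r_tallies[, 1])
  se <- sqrt(var(r_tallies[, 1]) / n_rep + sim$stderr^2)
  expect_lt(abs(m_r - sim$mean_dicentrics), 3.5 * se)
})

test_that("vanishing r0 with positive c_free suppresses all junctions", {
  dr <- simulate_dose_response(radiation_field("helium", 60), 0.5,
                               c(1, 2, 3), n_cells = 300, seed = 5,
                               kernel = rejoining_kernel(1e-6, 0.1))
  expect_true(all(dr$mean_dicentrics == 0))
})
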