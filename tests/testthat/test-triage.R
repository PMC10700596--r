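test_that("greedy leader clustering degenerates correctly and heads stay best-ranked", {
  # n identical molecules collapse to a single head, the best-ranked
  recs <- data.frame(id = letters[1:5], score = -(5:1))
  same <- replicate(5, c(1:20), simplify = FALSE)
  cl <- cluster_by_fingerprint(recs, same, 0.5)
  expect_equal(sum(cl$is_head), 1)
  expect_true(cl$is_head[1])
  # pairwise-dissimilar molecules each found a cluster
  apart <- lapply(0:4, function(k) k * 100 + 1:20)
  cl2 <- cluster_by_fingerprint(recs, apart, 0.5)
  expect_equal(sum(cl2$is_head), 5)
})

test_that("leader clustering equals a brute-force oracle on a 30-molecule fixture", {
  n <- 30
  fps <- random_fingerprints(n, seed = 6, n_bits = 40, universe = 120)
  recs <- data.frame(id = sprintf("m%02d", 1:n), score = seq(-n, -1))
  tc_mat <- outer(1:n, 1:n, Vectorize(function(i, j)
    memscreen:::tc_bits(fps[[i]], fps[[j]])))
  got <- cluster_by_fingerprint(recs, fps, 0.4)
  # independent oracle straight off the Tc matrix
  heads <- integer(0)
  assign <- integer(n)
  for (i in 1:n) {
    hit <- heads[tc_mat[i, heads] >= 0.4]
    if (length(hit) == 0) {
      heads <- c(heads, i)
      assign[i] <- i
    } else assign[i] <- hit[1]
  }
  expect_equal(which(got$is_head), heads)
  expect_equal(heads[got$cluster], assign)
  # cluster-structure invariants
  expect_true(all(tc_mat[heads, heads][upper.tri(diag(length(heads)))] < 0.4))
  for (i in seq_len(n)) expect_gte(tc_mat[i, assign[i]], ifelse(i %in% heads, 0, 0.4))
})

test_that("novelty filter removes at the inclusive Tc boundary with provenance", {
  recs <- data.frame(id = c("at_boundary", "below", "identical"))
  fps <- list(1:10, 200 + 1:10, 301:325)
  known <- list(k1 = c(1:7, 11:20),  # Tc to 1:10 = 7/20 = 0.35 exactly
                k2 = 301:325)        # identical to the third record
  nv <- novelty_filter(recs, fps, known, tc_cutoff = 0.35)
  expect_equal(nv$records$id, "below")
  expect_setequal(nv$removed$id, c("at_boundary", "identical"))
  expect_equal(nv$removed$offender[nv$removed$id == "identical"], "k2")
  expect_equal(nv$removed$max_tc[nv$removed$id == "at_boundary"], 0.35)
  # empty known set: everything retained, with a warning
  expect_warning(nv0 <- novelty_filter(recs, fps, list()), "empty")
  expect_equal(nrow(nv0$records), 3)
})

# a posed amide fixture: O(1)=C(2)-N(3)-C(4) with an extra carbon on C2 so
# both central atoms have degree >= 2; the O1-C2-N3-C4 dihedral is `angle`
amide_fixture <- function(angle_deg) {
  th <- angle_deg * pi / 180
  atoms <- data.frame(
    element = c("O", "C", "N", "C", "C"),
    x = c(-0.6, 0, 1.3, 1.9, -0.7),
    y = c(1.1, 0, 0, -1.25 * cos(th), -1.2),
    z = c(0, 0, 0, 1.25 * sin(th), 0))
  # dihedral O1-C2-N3-C4: O at +y, so C4 at -y is trans (180) when th = 0
  bonds <- data.frame(a1 = c(1, 2, 3, 2), a2 = c(2, 3, 4, 5),
                      order = c(2, 1, 1, 1))
  list(atoms = atoms, bonds = bonds)
}

test_that("strain lookup honours the inclusive TEU cutoff at rule angles", {
  rules <- list(list(id = "amide",
                     profile = data.frame(angle = c(0, 60, 120, 180),
                                          teu = c(1.5, 2.5, 2.5, 0))))
  # th = 0 places C4 trans to O -> dihedral 180 -> TEU 0
  s_trans <- measure_strain(amide_fixture(0), rules)
  expect_equal(s_trans$max_teu, 0)
  # th = 180 puts C4 cis to O -> dihedral 0 -> TEU exactly 1.5: passes
  s_cis <- measure_strain(amide_fixture(180), rules)
  expect_equal(s_cis$max_teu, 1.5, tolerance = 1e-6)
  sf <- strain_filter(list(cis = amide_fixture(180)), rules, teu_cutoff = 1.5)
  expect_true(sf$pass[["cis"]])
  # 6 degrees off cis -> 1.6 TEU: rejected
  s_over <- measure_strain(amide_fixture(174), rules)
  expect_equal(s_over$max_teu, 1.6, tolerance = 1e-3)
  sf2 <- strain_filter(list(x = amide_fixture(174)), rules, teu_cutoff = 1.5)
  expect_false(sf2$pass[["x"]])
})

test_that("rigid molecules pass strain trivially and uncovered dihedrals log as zero", {
  ring <- list(atoms = data.frame(element = rep("C", 6),
                                  x = cos(seq(0, 5) * pi / 3),
                                  y = sin(seq(0, 5) * pi / 3), z = 0),
               bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1))
  s <- measure_strain(ring)
  expect_equal(s$max_teu, 0)
  expect_equal(nrow(s$dihedrals), 0)
  # a plain C-C rotor matches no default rule: TEU 0, logged uncovered
  chain <- list(atoms = data.frame(element = rep("C", 4),
                                   x = c(0, 1.5, 2.2, 3.7),
                                   y = c(0, 0, 1.3, 1.3), z = 0),
                bonds = data.frame(a1 = 1:3, a2 = 2:4, order = 1))
  s2 <- measure_strain(chain)
  expect_equal(s2$max_teu, 0)
  expect_gte(s2$n_uncovered, 1)
})

test_that("per-dihedral strain equals hand-computed rule lookups", {
  rules <- default_torsion_rules()
  m <- amide_fixture(100)  # dihedral 80 off trans
  s <- measure_strain(m, rules)
  row <- s$dihedrals[s$dihedrals$rule_id == "amide", ]
  expect_equal(nrow(row), 1)
  prof <- rules[[which(vapply(rules, `[[`, character(1), "id") == "amide")]]$profile
  expect_equal(row$teu,
               stats::approx(prof$angle, prof$teu,
                             xout = abs(row$angle), rule = 2)$y)
})

test_that("interaction filter applies the geometric contact definitions", {
  tc <- make_toy_complex(50, 15, seed = 1)
  arg_n <- tc$receptor[tc$receptor$resname == "ARG", ]
  # carboxylate-like O placed 2.8 A from the +1 nitrogen: ionic contact
  pose <- data.frame(element = "O",
                     x = arg_n$x + 2.8, y = arg_n$y, z = arg_n$z,
                     formal_charge = -1)
  res <- interaction_filter(pose, tc$receptor,
                            data.frame(residue = "R1", type = "ionic"))
  expect_true(res$pass)
  expect_lte(res$contacts$distance, 4.0)
  # the same pair at 6 A fails
  pose6 <- pose; pose6$x <- arg_n$x + 6
  expect_false(interaction_filter(pose6, tc$receptor,
                                  data.frame(residue = "R1",
                                             type = "ionic"))$pass)
  expect_error(interaction_filter(pose, tc$receptor,
                                  data.frame(residue = "R999",
                                             type = "ionic")), "absent")
})

test_that("hydrogen bonds pass at the inclusive 3.5 A / 120 degree boundary", {
  # receptor backbone O of residue 2; engineered donor geometry
  tc <- make_toy_complex(50, 15, seed = 1)
  o2 <- tc$receptor[tc$receptor$resno == 2 & tc$receptor$atom_name == "O", ]
  acc <- c(o2$x, o2$y, o2$z)
  don <- acc + c(3.5, 0, 0)     # exactly 3.5 A
  # H between donor and acceptor, making a 130-degree D-H...A angle
  hx <- don + c(-0.7986, 0.6018, 0)
  pose <- data.frame(element = c("N", "H"),
                     x = c(don[1], hx[1]), y = c(don[2], hx[2]),
                     z = c(don[3], hx[3]), formal_charge = 0)
  res <- interaction_filter(pose, tc$receptor,
                            data.frame(residue = "T2", type = "hbond"),
                            bonds = cbind(1, 2))
  expect_true(res$pass)
  # push the donor past 3.5 A: fails
  pose_far <- pose; pose_far$x <- pose$x + 0.2
  expect_false(interaction_filter(pose_far, tc$receptor,
                                  data.frame(residue = "T2",
                                             type = "hbond"),
                                  bonds = cbind(1, 2))$pass)
})

test_that("the cascade telescopes and is a fixed point on its own survivors", {
  n <- 40
  fps <- random_fingerprints(n, seed = 12, n_bits = 30, universe = 400)
  names(fps) <- sprintf("m%02d", 1:n)
  ranked <- data.frame(id = names(fps), score = sort(stats::rnorm(n)))
  known <- random_fingerprints(3, seed = 99, n_bits = 30, universe = 400)
  rep1 <- run_triage(ranked, fps, known, top_n = 30, cluster_tc = 0.3,
                     novelty_tc = 0.35)
  for (k in seq_along(rep1$stages)[-1])
    expect_equal(rep1$stages[[k]]$n_in, rep1$stages[[k - 1]]$n_out)
  for (s in rep1$stages)
    expect_equal(s$n_in - s$n_out, length(s$rejected))
  # fixed point
  rep2 <- run_triage(rep1$survivors, fps, known, top_n = 30,
                     cluster_tc = 0.3, novelty_tc = 0.35)
  expect_equal(rep2$survivors$id, rep1$survivors$id)
  # relaxing the novelty cutoff never shrinks the survivor set
  rep4 <- run_triage(ranked, fps, known, top_n = 30, cluster_tc = 0.3,
                     novelty_tc = 1.1)
  expect_true(all(rep1$survivors$id %in% rep4$survivors$id))
  # JSON serialisation keeps the stage log
  f <- tempfile(fileext = ".json")
  write_triage_report(rep1, f)
  back <- jsonlite::read_json(f)
  expect_equal(length(back$stages), length(rep1$stages))
  expect_equal(unlist(back$survivors), rep1$survivors$id)
})
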