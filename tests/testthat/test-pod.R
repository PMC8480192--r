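prof <- function(dh = "H", da = "R", mn = c("A", "G", "N"), trp = "A",
                 tyr = "F", tail = 8, ph = "H") {
  structure(list(distal_his = dh, distal_arg = da, proximal_his = ph,
                 mn_site_1 = mn[1], mn_site_2 = mn[2], mn_site_3 = mn[3],
                 trp_lip = trp, tyr_tc = tyr, c_tail_length = tail),
            class = "pod_profile")
}

test_that("profile extraction reads mapped columns and counts the tail", {
  sm <- synthetic_pod_site_map()
  seq <- paste0(strrep("A", 4), "H", strrep("A", 4), "R",
                strrep("A", 9), "H", strrep("A", 4), "E",
                strrep("A", 4), "E", strrep("A", 4), "D",
                strrep("A", 4), "W", strrep("A", 4), "F",
                strrep("A", 5),
                paste0(strrep("A", 6), "--", strrep("A", 4)), strrep("-", 18))
  msa <- c(s1 = substr(seq, 1, 80))
  p <- extract_profile(msa, sm, "s1")
  expect_equal(p$distal_his, "H")
  expect_equal(p$distal_arg, "R")
  expect_equal(c(p$mn_site_1, p$mn_site_2, p$mn_site_3), c("E", "E", "D"))
  expect_equal(p$trp_lip, "W")
  expect_equal(p$c_tail_length, 10)   # 12 positions, 2 gaps
  expect_error(extract_profile(msa, sm, "nope"), "not in alignment")
})

test_that("gaps at catalytic columns are recorded, not errors", {
  sm <- synthetic_pod_site_map()
  s <- strrep("A", 80)
  substr(s, sm$trp_lip, sm$trp_lip) <- "-"
  p <- extract_profile(c(x = s), sm, "x")
  expect_equal(p$trp_lip, "-")
})

test_that("classifier reproduces the eight exemplar heme-region layouts", {
  # LiP: His/Arg distal, no Mn site, exposed Trp
  expect_equal(as.character(classify_pod(prof(trp = "W"))), "LiP")
  # MnP-l / MnP-s: Glu/Glu/Asp site, tail length separates them
  expect_equal(as.character(classify_pod(prof(mn = c("E", "E", "D"),
                                              tail = 20))), "MnP-l")
  expect_equal(as.character(classify_pod(prof(mn = c("E", "E", "D"),
                                              tail = 8))), "MnP-s")
  # VP: Trp plus the MnP site
  expect_equal(as.character(classify_pod(prof(mn = c("E", "E", "D"),
                                              trp = "W"))), "VP")
  # GP: lysine blocks the cation site, no Trp
  expect_equal(as.character(classify_pod(prof(mn = c("K", "G", "N")))), "GP")
  # alternative Mn sites
  expect_equal(as.character(classify_pod(prof(mn = c("E", "S", "D")))),
               "MnP-ESD")
  expect_equal(as.character(classify_pod(prof(mn = c("D", "G", "D")))),
               "MnP-DGD")
  expect_equal(as.character(classify_pod(prof(mn = c("D", "E", "D")))),
               "MnP-DED")
  # NPOD: His/His distal pair with surface Tyr
  np <- classify_pod(prof(da = "H", mn = c("E", "A", "Y"), tyr = "Y"))
  expect_equal(as.character(np), "NPOD")
})

test_that("atypical VP and unclassified rules behave as documented", {
  # Trp + two-acidic triad is VP-a
  expect_equal(as.character(classify_pod(prof(mn = c("E", "S", "D"),
                                              trp = "W"))), "VP-a")
  # non-His/Arg, non-His/His distal pair is unclassified
  expect_equal(as.character(classify_pod(prof(da = "K"))), "unclassified")
  expect_equal(as.character(classify_pod(prof(dh = "-"))), "unclassified")
  # surface Tyr alone raises a flag, not a type
  g <- classify_pod(prof(tyr = "Y"))
  expect_equal(as.character(g), "GP")
  expect_true(attr(g, "tyr_flag"))
})

test_that("classification is total and ignores non-decisive residues", {
  set.seed(40)
  aa <- c("A", "R", "N", "D", "E", "H", "K", "W", "Y", "-")
  for (i in 1:50) {
    p <- prof(dh = sample(aa, 1), da = sample(aa, 1),
              mn = sample(aa, 3, replace = TRUE), trp = sample(aa, 1),
              tyr = sample(aa, 1), tail = sample(0:30, 1))
    ty <- classify_pod(p)
    expect_true(as.character(ty) %in% pod_types())
    # proximal His is not decisive
    p2 <- p; p2$proximal_his <- "Q"
    expect_equal(as.character(classify_pod(p2)), as.character(ty))
  }
})

test_that("marginal reconstruction matches exhaustive enumeration on 4 states", {
  alphabet <- c("A", "R", "N", "D")
  m <- aa_model("uniform", alphabet = alphabet)
  tr <- read_timetree("((A:0.3,B:0.2):0.2,C:0.4);", "subs")
  msa <- c(A = "AR", B = "AN", C = "DR")
  post <- marginal_asr(tr, msa, 1:2, model = m)
  for (col in 1:2) {
    tips <- setNames(substr(msa, col, col), names(msa))
    oracle <- oracle_asr_posterior(tr, tips, alphabet, m$Q, m$freqs)
    expect_equal(unname(post[, col, ]), unname(oracle), tolerance = 1e-10)
    expect_equal(rowSums(post[, col, ]), setNames(rep(1, 2), rownames(post[, col, ])),
                 tolerance = 1e-9)
  }
})

test_that("reconstruction pulls to consensus and saturates to stationarity", {
  m <- aa_model("WAG")
  tr <- read_timetree("(A:0.05,B:0.05);", "subs")
  post <- marginal_asr(tr, c(A = "H", B = "H"), 1, model = m)
  expect_gt(post[1, 1, "H"], m$freqs[["H"]])
  expect_equal(names(which.max(post[1, 1, ])), "H")
  # saturation
  tr2 <- read_timetree("(A:400,B:400);", "subs")
  post2 <- marginal_asr(tr2, c(A = "H", B = "H"), 1, model = m)
  expect_equal(unname(post2[1, 1, ]), unname(m$freqs), tolerance = 1e-4)
  # gaps are missing data
  post3 <- marginal_asr(tr, c(A = "H", B = "-"), 1, model = m)
  expect_equal(names(which.max(post3[1, 1, ])), "H")
})

test_that("ancestor typing composes reconstruction and the rule set", {
  sm <- synthetic_pod_site_map()
  tr <- read_timetree("((s1:0.05,s2:0.05):0.05,(s3:0.05,s4:0.05):0.05);",
                      "subs")
  types <- setNames(rep("VP", 4), paste0("s", 1:4))
  aln <- simulate_pod_alignment(tr, types, sm, seed = 41)
  post <- marginal_asr(tr, aln, unlist(sm))
  anc <- classify_ancestors(post, sm)
  expect_true(all(anc$type == "VP"))
  # high-confidence columns give no runner-up
  expect_true(all(is.na(anc$runner_up[anc$min_prob >= 0.7])))
  # forced ambiguity reports a runner-up
  fake <- post
  fake[1, as.character(sm$trp_lip), ] <- 0
  fake[1, as.character(sm$trp_lip), c("W", "A")] <- c(0.55, 0.45)
  anc2 <- classify_ancestors(fake, sm)
  expect_false(is.na(anc2$runner_up[1]))
})

test_that("type origins report first appearances and convergent origins", {
  tr <- read_timetree("((A:1,B:1):1,(C:1,D:1):1);")
  ids <- node_ids(tr)
  one <- setNames(rep("MnP-s", length(ids)), ids)
  org <- map_type_origins(tr, one)
  expect_equal(nrow(org), 1)
  expect_equal(org$node, "N1")
  expect_true(is.na(org$parent_type))

  # single transition on the branch to the (C,D) clade ancestor
  tt <- one
  tt[c("N3", "C", "D")] <- "MnP-ESD"
  org2 <- map_type_origins(tr, tt)
  esd <- org2[org2$type == "MnP-ESD", ]
  expect_equal(esd$node, "N3")
  expect_equal(esd$age_My, 1)
  expect_equal(esd$parent_type, "MnP-s")

  # two independent origins of the same type (convergence)
  tt2 <- one
  tt2[c("A", "C")] <- "MnP-ESD"
  org3 <- map_type_origins(tr, tt2)
  expect_equal(sum(org3$type == "MnP-ESD"), 2)
})
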