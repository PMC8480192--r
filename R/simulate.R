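#' Simulation preset for the full pipeline
#'
#' Bundles every parameter of the synthetic-data generators. The default
#' mirrors the dimensions of the study system this package targets: 52
#' tips, 192-My root age (the dated crown of the clade), 62 focal
#' (PCWDE-like) plus 24 background gene families, six lifestyles, and a
#' baseline gain/loss rate of 0.002 events per gene per My. Lifestyle
#' signal enters through per-family, per-lifestyle gain-rate multipliers
#' so that ancestral counts and lifestyles remain jointly coherent
#' ground truth.
#'
#' @param n_tips Number of extant species.
#' @param root_age_My Root age after rescaling.
#' @param n_focal,n_background Numbers of focal and background families.
#' @param lambda Baseline birth = death rate (per gene per My).
#' @param q Lifestyle Mk rate (per My, rate to each other state).
#' @param n_signal Number of focal families carrying lifestyle signal.
#' @param signal_gain Gain-rate multiplier of a signal family in its
#'   associated lifestyle.
#' @param root_mean Mean root copy number (root counts are 1 + Poisson).
#' @param fast_multiplier Overall rate multiplier (birth and death alike)
#'   applied to the signal families, emulating fast-evolving families;
#'   default 1 (no overall speed-up).
#' @param seed RNG seed (mandatory).
#' @return List of class `decay_preset`.
#' @export
decay_preset <- function(n_tips = 52, root_age_My = 192, n_focal = 62,
                         n_background = 24, lambda = 0.002, q = 0.001,
                         n_signal = 7, signal_gain = 4, root_mean = 5,
                         fast_multiplier = 1, seed = 1) {
  stopifnot(n_tips >= 2, lambda >= 0, q >= 0, n_signal <= n_focal,
            !is.null(seed))
  focal <- sprintf("PCWDE%02d", seq_len(n_focal))
  backg <- sprintf("BG%02d", seq_len(n_background))
  fams <- c(focal, backg)
  g <- matrix(1, length(fams), 6,
              dimnames = list(fams, lifestyle_levels()))
  # the first n_signal focal families each favour one lifestyle
  # (cycled over the six lifestyles)
  sig <- focal[seq_len(n_signal)]
  for (i in seq_len(n_signal))
    g[sig[i], ((i - 1) %% 6) + 1] <- signal_gain
  rate_mult <- setNames(rep(1, length(fams)), fams)
  rate_mult[sig] <- fast_multiplier
  structure(list(n_tips = n_tips, root_age_My = root_age_My,
                 families = fams, roles = setNames(
                   rep(c("focal", "background"), c(n_focal, n_background)),
                   fams),
                 signal_families = sig, gain = g,
                 rate_multiplier = rate_mult, lambda = lambda, q = q,
                 root_mean = root_mean, seed = seed),
            class = "decay_preset")
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree rescaled so that the root age is exactly
#' `root_age_My`. Tips are labelled `sp01`, `sp02`, ... and internal
#' nodes `N1..` in preorder.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age_My Target root age.
#' @param seed RNG seed.
#' @return A `phylo` time tree.
#' @export
simulate_tree <- function(n_tips, root_age_My, seed) {
  stopifnot(n_tips >= 2)
  with_seed(seed, {
    tree <- if (n_tips == 2) {
      ape::read.tree(text = "(sp01:1,sp02:1);")
    } else {
      ape::rphylo(n_tips, birth = 1, death = 0)
    }
    tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
    depth <- max(node_depths(tree)[seq_len(n_tips)])
    tree$edge.length <- tree$edge.length * root_age_My / depth
    tree$node.label <- NULL
    tree <- name_internal_nodes(tree)
    attr(tree, "lengths_unit") <- "My"
    tree
  })
}

#' Simulate lifestyle evolution on a tree (Mk model)
#'
#' The root state is drawn uniformly from the six lifestyles; states then
#' evolve along each branch under the symmetric 6-state Markov process
#' with rate `q` to each other state (transition probability to a given
#' different state over time t: \eqn{1/6 - e^{-6qt}/6}).
#'
#' @param tree Time tree.
#' @param q Mk rate (per My).
#' @param seed RNG seed.
#' @return Named lifestyle vector over all nodes (tips and ancestors):
#'   the full ground truth.
#' @export
simulate_lifestyles <- function(tree, q, seed) {
  stopifnot(q >= 0)
  k <- 6
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    states <- integer(n_node)
    root <- n_tip + 1L
    states[root] <- sample.int(k, 1)
    for (e in rev(postorder_edges(tree))) {   # parent before child
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      p_other <- (1 - exp(-k * q * t)) / k
      pr <- rep(p_other, k)
      pr[states[par]] <- 1 - (k - 1) * p_other
      states[chi] <- sample.int(k, 1, prob = pr)
    }
    setNames(lifestyle_levels()[states], node_ids(tree))
  })
}

# Exact (Gillespie) simulation of a linear birth-death process over one
# branch: per-gene birth rate b, death rate d, duration t.
.gillespie_bd <- function(n0, b, d, t, cap = 5000L) {
  n <- n0
  now <- 0
  repeat {
    rate <- n * (b + d)
    if (rate == 0) return(n)
    now <- now + rexp(1, rate)
    if (now > t) return(n)
    if (runif(1) < b / (b + d)) n <- n + 1L else n <- n - 1L
    if (n >= cap) stop("count cap exceeded in birth-death simulation")
  }
}

#' Simulate gene-family counts with lifestyle-linked rates
#'
#' Root counts are drawn as 1 + Poisson(`root_mean` - 1); along each
#' branch the copy number evolves by an exact event-level linear
#' birth-death simulation with per-gene birth rate
#' `lambda * g[family, lifestyle(child)]` and death rate `lambda`, where
#' the multiplier matrix `g` comes from the preset. Ancestral counts at
#' every node are recorded as ground truth.
#'
#' @param tree Time tree.
#' @param lifestyles Named lifestyle vector over all nodes (from
#'   [simulate_lifestyles()]).
#' @param preset A [decay_preset()].
#' @param seed RNG seed (defaults to the preset's).
#' @return List with `tip_counts` (species x families integer matrix,
#'   role attribute set) and `node_counts` (all nodes x families).
#' @export
simulate_counts <- function(tree, lifestyles, preset, seed = preset$seed) {
  with_seed(seed, {
    fams <- preset$families
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    ids <- node_ids(tree)
    counts <- matrix(0L, n_node, length(fams),
                     dimnames = list(ids, fams))
    root <- n_tip + 1L
    counts[root, ] <- 1L + rpois(length(fams), max(preset$root_mean - 1, 0))
    ord <- rev(postorder_edges(tree))
    for (f in seq_along(fams)) {
      for (e in ord) {
        par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
        ls <- lifestyles[[ids[chi]]]
        base <- preset$lambda * preset$rate_multiplier[[fams[f]]]
        b <- base * preset$gain[fams[f], ls]
        counts[chi, f] <- .gillespie_bd(counts[par, f], b, base,
                                        tree$edge.length[e])
      }
    }
    tips <- counts[seq_len(n_tip), , drop = FALSE]
    attr(tips, "role") <- preset$roles
    list(tip_counts = tips, node_counts = counts)
  })
}

# Catalytic-column residue templates per POD type. Columns:
# distal_his, distal_arg, mn1, mn2, mn3, trp_lip, tyr_tc; plus whether
# the type carries a long C-terminal tail.
.pod_templates <- list(
  "LiP"     = list(res = c("H","R","A","G","N","W","F"), long_tail = FALSE),
  "VP"      = list(res = c("H","R","E","E","D","W","F"), long_tail = FALSE),
  "VP-a"    = list(res = c("H","R","E","S","D","W","F"), long_tail = FALSE),
  "MnP-s"   = list(res = c("H","R","E","E","D","A","F"), long_tail = FALSE),
  "MnP-l"   = list(res = c("H","R","E","E","D","A","F"), long_tail = TRUE),
  "MnP-ESD" = list(res = c("H","R","E","S","D","A","F"), long_tail = FALSE),
  "MnP-DGD" = list(res = c("H","R","D","G","D","A","F"), long_tail = FALSE),
  "MnP-DED" = list(res = c("H","R","D","E","D","A","F"), long_tail = FALSE),
  "NPOD"    = list(res = c("H","H","E","A","Y","A","Y"), long_tail = FALSE),
  "GP"      = list(res = c("H","R","K","G","N","A","F"), long_tail = FALSE)
)

#' Default site map of the synthetic POD alignments
#'
#' @param length Total alignment length (default 80; the last 30 columns
#'   form the tail region after the anchor at column 50).
#' @return A [pod_site_map()].
#' @export
synthetic_pod_site_map <- function(length = 80) {
  pod_site_map(distal_his = 5, distal_arg = 10, proximal_his = 20,
               mn_site_1 = 25, mn_site_2 = 30, mn_site_3 = 35,
               trp_lip = 40, tyr_tc = 45, tail_anchor = 50,
               alignment_length = length)
}

#' Simulate a toy POD alignment with planted catalytic types
#'
#' Non-catalytic columns evolve under the substitution model along the
#' tree (root drawn from the stationary frequencies); the catalytic
#' columns of every tip are then overwritten with the residue template
#' of its planted type, and the tail region after the anchor is gapped
#' down to a short (8) or long (20) tail according to the type.
#'
#' @param subst_tree Tree with branch lengths in substitutions/site.
#' @param tip_types Named POD type per tip (from [pod_types()]).
#' @param site_map Site map (default [synthetic_pod_site_map()]).
#' @param seed RNG seed.
#' @param model Substitution model for the neutral columns.
#' @param aln_length Alignment length.
#' @return Named character vector of aligned sequences.
#' @export
simulate_pod_alignment <- function(subst_tree, tip_types,
                                   site_map = synthetic_pod_site_map(),
                                   seed = 1, model = aa_model("WAG"),
                                   aln_length = 80) {
  bad <- setdiff(unlist(tip_types), names(.pod_templates))
  if (length(bad) > 0) stop("unknown POD type: ", paste(bad, collapse = ", "))
  miss <- setdiff(subst_tree$tip.label, names(tip_types))
  if (length(miss) > 0) stop("tips without planted type")
  with_seed(seed, {
    n_tip <- length(subst_tree$tip.label)
    n_node <- n_tip + subst_tree$Nnode
    ns <- length(model$alphabet)
    Pm <- lapply(subst_tree$edge.length, function(t) .aa_pmat(model, t))
    S <- matrix(0L, n_node, aln_length)
    root <- n_tip + 1L
    S[root, ] <- sample.int(ns, aln_length, replace = TRUE, prob = model$freqs)
    for (e in rev(postorder_edges(subst_tree))) {
      par <- subst_tree$edge[e, 1]; chi <- subst_tree$edge[e, 2]
      for (j in seq_len(aln_length))
        S[chi, j] <- sample.int(ns, 1, prob = Pm[[e]][S[par, j], ])
    }
    seqs <- apply(S[seq_len(n_tip), , drop = FALSE], 1, function(r)
      paste0(model$alphabet[r], collapse = ""))
    names(seqs) <- subst_tree$tip.label
    cat_cols <- c(site_map$distal_his, site_map$distal_arg,
                  site_map$mn_site_1, site_map$mn_site_2,
                  site_map$mn_site_3, site_map$trp_lip, site_map$tyr_tc)
    tail_start <- site_map$tail_anchor + 1L
    tail_len <- aln_length - site_map$tail_anchor
    for (tp in names(seqs)) {
      tmpl <- .pod_templates[[tip_types[[tp]]]]
      s <- strsplit(seqs[[tp]], "")[[1]]
      s[cat_cols] <- tmpl$res
      s[site_map$proximal_his] <- "H"
      keep <- if (tmpl$long_tail) min(20L, tail_len) else min(8L, tail_len)
      if (tail_len > keep)
        s[(tail_start + keep):aln_length] <- "-"
      seqs[[tp]] <- paste0(s, collapse = "")
    }
    seqs
  })
}

#' Generate a complete synthetic input bundle
#'
#' Runs [simulate_tree()], [simulate_lifestyles()] and
#' [simulate_counts()] under one preset, optionally writing the files
#' the readers of this package consume (Newick, TSVs) to a directory.
#'
#' @param preset A [decay_preset()].
#' @param dir Optional output directory.
#' @return List with `tree`, `lifestyles` (all nodes), `tip_counts`,
#'   `node_counts`, and the `preset`.
#' @export
simulate_bundle <- function(preset = decay_preset(), dir = NULL) {
  tree <- simulate_tree(preset$n_tips, preset$root_age_My, preset$seed)
  lifestyles <- simulate_lifestyles(tree, preset$q, preset$seed + 1)
  cs <- simulate_counts(tree, lifestyles, preset, seed = preset$seed + 2)
  out <- list(tree = tree, lifestyles = lifestyles,
              tip_counts = cs$tip_counts, node_counts = cs$node_counts,
              preset = preset)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(tree, file.path(dir, "tree.nwk"))
    write_tsv(cs$tip_counts, file.path(dir, "counts.tsv"),
              rownames_as = "species")
    tips <- lifestyles[tree$tip.label]
    write_tsv(data.frame(id = names(tips), lifestyle = unname(tips)),
              file.path(dir, "lifestyles.tsv"), rownames_as = NULL)
    write_tsv(data.frame(id = names(lifestyles),
                         lifestyle = unname(lifestyles)),
              file.path(dir, "lifestyles_truth.tsv"), rownames_as = NULL)
  }
  out
}
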