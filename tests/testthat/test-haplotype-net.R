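test_that("canonical rotation is invariant over the rotation/strand orbit", {
  # enumeration by hand: rotations of GTAC and of its reverse complement
  # (GTAC again) are {GTAC, TACG, ACGT, CGTA}; the minimum is ACGT
  expect_equal(canonical_rotation("GTAC"), "ACGT")

  set.seed(1101)
  s <- rand_seq(200)
  canon <- canonical_rotation(s)
  for (i in 1:10) {
    r <- sample.int(nchar(s), 1)
    rot <- paste0(substr(s, r, nchar(s)), substr(s, 1, r - 1))
    if (i %% 2) rot <- rc_oracle(rot)
    expect_equal(canonical_rotation(rot), canon)
  }
})

test_that("member preparation drops DTR-less and mismatched-DTR members", {
  set.seed(1102)
  core <- rand_seq(480)
  exact12 <- paste0(core, substr(core, 1, 12))
  mm12 <- paste0(core, mutate_seq(substr(core, 1, 12), 1))
  none <- rand_seq(492)
  prep <- prepare_members(c(a = exact12, b = mm12, c = none))
  expect_equal(prep$member_id, "a")
  expect_equal(prep$dtr_length, 12L)
  expect_equal(nchar(prep$seq), 480L)
  expect_equal(prep$seq, canonical_rotation(core))
})

test_that("long-indel filtering removes >= 2 bp events only", {
  msa <- rbind(
    ref  = c("A", "C", "G", "T", "A", "C"),
    del3 = c("A", "-", "-", "-", "A", "C"),
    two1 = c("A", "-", "G", "T", "-", "C"),
    same = c("A", "C", "G", "T", "A", "C"))
  attr(msa, "reference") <- "ref"
  out <- filter_msa_members(msa)
  expect_setequal(rownames(out), c("ref", "two1", "same"))

  ident <- msa[c("ref", "same"), ]
  attr(ident, "reference") <- "ref"
  expect_equal(nrow(filter_msa_members(ident)), 2L)
})

test_that("haplotype collapse treats gaps as a fifth state", {
  msa <- rbind(m1 = c("A", "C", "G"), m2 = c("A", "C", "G"),
               m3 = c("A", "T", "G"), m4 = c("A", "-", "G"))
  ht <- collapse_haplotypes(msa)
  expect_equal(nrow(ht$signatures), 3L)
  expect_setequal(ht$members[[1]], c("m1", "m2"))
  d <- hap_distances(ht$signatures)
  expect_true(all(d[upper.tri(d)] == 1))

  ten <- matrix("A", 10, 4, dimnames = list(paste0("m", 1:10), NULL))
  expect_equal(nrow(collapse_haplotypes(ten)$signatures), 1L)
})

test_that("clonal members at random rotations collapse to one haplotype", {
  tree <- data.frame(parent = "H", child = "H2", n_mut = 1)
  pop <- gen_haplotype_population(1103, 500, tree,
                                 members_per_hap = c(H = 5, H2 = 0))
  prep <- prepare_members(pop$members)
  expect_equal(nrow(prep), 5L)
  msa <- align_members(stats::setNames(prep$seq, prep$member_id))
  ht <- collapse_haplotypes(msa)
  expect_equal(nrow(ht$signatures), 1L)
  # within-haplotype identity is exactly 100%
  expect_equal(length(unique(prep$seq)), 1L)
})

test_that("median-joining network handles trivial and star topologies", {
  # two haplotypes at distance 3: one edge, nothing to mediate
  sig2 <- rbind(A = c("A", "A", "A", "C"), B = c("T", "T", "T", "C"))
  net2 <- median_joining_network(sig2)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$n_diff, 3L)
  expect_false(any(net2$nodes$is_median))

  # single haplotype: one node, no edges
  net1 <- median_joining_network(rbind(A = c("A", "C")))
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)

  # three haplotypes off a shared background at three distinct columns:
  # the enumerated optimum is a star with one median and three 1-edges
  bg <- c("C", "C", "C", "G", "G")
  sigs <- rbind(A = replace(bg, 1, "G"), B = replace(bg, 2, "G"),
                C = replace(bg, 3, "G"))
  net <- median_joining_network(sigs)
  expect_equal(sum(net$nodes$is_median), 1L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$n_diff == 1L))
  med <- net$nodes$node_id[net$nodes$is_median]
  expect_true(all(net$edges$from == med | net$edges$to == med))
})

test_that("planted mutation trees are recovered as paths of matching weight", {
  tree <- data.frame(parent = c("R", "R", "B"), child = c("A", "B", "C"),
                     n_mut = c(1, 2, 1))
  pop <- gen_haplotype_population(1104, 600, tree, members_per_hap = 2)
  prep <- prepare_members(pop$members)
  msa <- filter_msa_members(align_members(stats::setNames(prep$seq, prep$member_id)))
  ht <- collapse_haplotypes(msa)
  # map planted haplotype labels to collapsed ids
  lab <- vapply(names(ht$members), function(h) {
    unique(pop$truth$hap_of_member[ht$members[[h]]])
  }, "")
  hap_id_of <- stats::setNames(names(lab), lab)
  net <- median_joining_network(ht)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$node_id)
  for (i in seq_len(nrow(tree))) {
    dpath <- igraph::distances(g, v = hap_id_of[[tree$parent[i]]],
                               to = hap_id_of[[tree$child[i]]],
                               weights = igraph::E(g)$n_diff)[1, 1]
    expect_equal(unname(dpath), tree$n_mut[i])
  }
})

test_that("network weight never exceeds the observed MST on tree-like sets", {
  # random infinite-sites sets: each column mutates once on a random tree
  set.seed(1105)
  for (rep in 1:20) {
    n_hap <- sample(2:5, 1)
    sigs <- matrix("C", 1, 0)
    for (h in seq_len(n_hap - 1L)) {
      parent <- sigs[sample.int(nrow(sigs), 1), ]
      n_new <- sample(1:3, 1)
      child <- c(parent, rep("C", n_new))
      child[length(parent) + seq_len(n_new)] <- "G"
      sigs <- cbind(sigs, matrix("C", nrow(sigs), n_new))
      sigs <- rbind(sigs, child)
    }
    rownames(sigs) <- paste0("H", seq_len(nrow(sigs)))
    net <- median_joining_network(sigs)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$node_id)
    # every observed haplotype is reachable from every other
    expect_equal(igraph::components(g)$no, 1L)
    if (nrow(sigs) >= 2) {
      expect_lte(sum(net$edges$n_diff), mst_weight(hap_distances(sigs)))
    }
  }
})

test_that("the transmission clock scales the genome rate to plasmid length", {
  zero <- transmission_window(0, 5600)
  expect_equal(zero$lower, 0)
  expect_equal(zero$upper, 10)

  lam <- 30 * 5600 / 1670000
  two <- transmission_window(2, 5600)
  expect_equal(two$years, 2 / lam)
  expect_equal(round(two$years, 1), 19.9)

  expect_error(transmission_window(0, 0), "positive")
})

test_that("haplotype and network exports write well-formed files", {
  sigs <- rbind(A = c("A", "C"), B = c("A", "G"))
  msa <- rbind(m1 = sigs["A", ], m2 = sigs["B", ], m3 = sigs["B", ])
  ht <- collapse_haplotypes(msa)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes(ht, f1)
  expect_equal(nrow(utils::read.delim(f1)), 2L)

  net <- median_joining_network(ht)
  pre <- withr::local_tempfile()
  write_mj_network(net, pre)
  expect_true(file.exists(paste0(pre, ".graphml")))

  f2 <- withr::local_tempfile(fileext = ".nex")
  write_haplotype_nexus(ht, f2)
  expect_match(readLines(f2)[1], "#NEXUS")
})
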