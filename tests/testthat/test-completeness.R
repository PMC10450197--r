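test_that("DTR detection agrees with the brute-force all-length oracle", {
  set.seed(901)
  x <- rand_seq(470)
  planted <- paste0(x, substr(x, 1, 15))
  hit <- find_dtr(planted)
  expect_true(hit$found)
  expect_equal(hit$length, 15L)
  expect_equal(hit$n_mismatch, 0L)

  with_mm <- paste0(x, mutate_seq(substr(x, 1, 20), 1))
  # plant a 20-bp terminal repeat carrying one substitution
  hm <- find_dtr(paste0(substr(x, 1, 20), substr(x, 21, 470),
                        mutate_seq(substr(x, 1, 20), 1)))
  expect_true(hm$found)
  expect_equal(hm$length, 20L)
  expect_equal(hm$n_mismatch, 1L)

  for (i in 1:30) {
    s <- rand_seq(sample(100:800, 1))
    mine <- find_dtr(s)
    oracle <- brute_dtr(s)
    expect_equal(mine$found, oracle$found)
    if (mine$found) {
      expect_equal(mine$length, oracle$length)
      expect_equal(mine$n_mismatch, oracle$n_mismatch)
    }
  }
})

test_that("DTR round-trip recovers a duplicated 15-bp terminus", {
  set.seed(902)
  for (i in 1:20) {
    circ <- rand_seq(2000)
    lin <- paste0(circ, substr(circ, 1, 15))
    hit <- find_dtr(lin, max_mismatch = 0)
    expect_true(hit$found)
    expect_equal(hit$length, 15L)
  }
})

test_that("read pairs confirm circularity only with end-anchored mates", {
  set.seed(903)
  circ <- rand_seq(4000)
  pls <- paste0(circ, substr(circ, 1, 20))
  # a pair spanning the junction: one mate near each end of the trimmed PLS
  good <- data.frame(read1 = substr(circ, 3870, 3969),
                     read2 = revcomp(substr(circ, 40, 139)),
                     stringsAsFactors = FALSE)
  expect_true(confirm_circular_by_reads(pls, good))

  interior <- data.frame(read1 = substr(circ, 1800, 1899),
                         read2 = substr(circ, 2100, 2199),
                         stringsAsFactors = FALSE)
  expect_false(confirm_circular_by_reads(pls, interior))

  # a mate soft-trimmed to 85% coverage fails the coverage filter
  trimmed <- data.frame(read1 = paste0(rand_seq(15), substr(circ, 1, 85)),
                        read2 = substr(circ, 3870, 3969),
                        stringsAsFactors = FALSE)
  expect_false(confirm_circular_by_reads(pls, trimmed))

  expect_warning(res <- confirm_circular_by_reads(pls, good[0, ]), "no reads")
  expect_false(res)
  expect_error(confirm_circular_by_reads(rand_seq(1000), good), "DTR")
})

test_that("FASTG writing and parsing round-trip the graph", {
  fx <- gen_assembly_fixture(904, plasmid_len = 6000, fraction_observed = 1)
  f <- withr::local_tempfile(fileext = ".fastg")
  write_fastg(fx$graph, f)
  back <- parse_fastg(f)
  ord <- order(back$nodes$node_id)
  ord0 <- order(fx$graph$nodes$node_id)
  expect_equal(back$nodes$node_id[ord], fx$graph$nodes$node_id[ord0])
  expect_equal(back$nodes$seq[ord], fx$graph$nodes$seq[ord0])
  key <- function(e) sort(paste(e$from, e$from_orient, e$to, e$to_orient))
  expect_equal(key(back$edges), key(fx$graph$edges))
})

test_that("shortest circular path picks the bp-minimal cycle", {
  set.seed(905)
  # single node with a self-edge
  loop <- assembly_graph(
    data.frame(node_id = "n1", seq = rand_seq(3000), abundance = 10),
    data.frame(from = "n1", from_orient = "+", to = "n1", to_orient = "+"))
  p1 <- shortest_circular_path(loop, "n1")
  expect_equal(nrow(p1$steps), 1L)
  expect_equal(p1$total_len, 3000)

  # anchor on a dead-end branch has no cycle
  dead <- assembly_graph(
    data.frame(node_id = c("a", "b"), seq = c(rand_seq(1000), rand_seq(1000)),
               abundance = 10),
    data.frame(from = "a", from_orient = "+", to = "b", to_orient = "+"))
  expect_null(shortest_circular_path(dead, "a"))

  # two cycles through the anchor: 9 kb beats 14 kb (all simple cycles of
  # this toy graph: X-A-B-X = 2+3+4 and X-C-D-X = 2+5+7)
  nodes <- data.frame(
    node_id = c("X", "A", "B", "C", "D"),
    seq = c(rand_seq(2000), rand_seq(3000), rand_seq(4000),
            rand_seq(5000), rand_seq(7000)),
    abundance = 10, stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("X", "A", "B", "X", "C", "D"), from_orient = "+",
    to = c("A", "B", "X", "C", "D", "X"), to_orient = "+",
    stringsAsFactors = FALSE)
  g <- assembly_graph(nodes, edges)
  p <- shortest_circular_path(g, "X")
  expect_equal(p$total_len, 9000)
  expect_setequal(unique(p$steps$node), c("X", "A", "B"))

  expect_error(shortest_circular_path(g, "missing"), "absent")
})

test_that("copy-number formula and orientation exception are applied", {
  set.seed(906)
  # A = 10, no off-path neighbors: C = 1
  fx <- gen_assembly_fixture(907, plasmid_len = 8000, fraction_observed = 1,
                             noise = 0, n_decoys = 0)
  p <- shortest_circular_path(fx$graph, fx$anchors)
  cn <- path_copy_numbers(fx$graph, p, fx$truth$base_abundance)
  expect_true(all(abs(cn$C - 1) < 1e-9))
  expect_false(any(cn$multi_copy))

  # printed-formula arithmetic: A = 30, Ap = 8, Af = 12, Abase = 10 -> 2.2
  nodes <- data.frame(
    node_id = c("n", "m", "p1", "f1", "f2"),
    seq = c(rand_seq(1000), rand_seq(1000), rand_seq(500), rand_seq(500),
            rand_seq(500)),
    abundance = c(30, 10, 8, 5, 7), stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("n", "m", "p1", "n", "n"), from_orient = "+",
    to = c("m", "n", "n", "f1", "f2"), to_orient = "+",
    stringsAsFactors = FALSE)
  g <- assembly_graph(nodes, edges)
  path <- shortest_circular_path(g, c("n", "m"))
  i <- which(path$steps$node == "n")
  cc <- node_copy_number(g, path, i, base_abundance = 10)
  expect_equal(cc$C, 2.2)
  expect_true(cc$multi_copy)
  expect_error(node_copy_number(g, path, i, base_abundance = 0), "positive")

  # a node traversed in opposite orientations needs C > 2.8
  fake <- structure(list(steps = data.frame(node = c("n", "m", "n"),
                                            orient = c("+", "+", "-"),
                                            stringsAsFactors = FALSE)),
                    class = "circular_path")
  cc22 <- node_copy_number(g, fake, 1, base_abundance = 10)
  expect_equal(cc22$C, 2.2)
  expect_false(cc22$multi_copy)
})

test_that("copy-number classification stays >= 95% right under 10% noise", {
  correct <- 0L; total <- 0L
  for (seed in 1:5) {
    mult <- sample(1:3, 8, replace = TRUE)
    fx <- gen_assembly_fixture(910 + seed, plasmid_len = 8000,
                               fraction_observed = 1, n_anchor_nodes = 8,
                               copy_plan = mult, noise = 0.1, n_decoys = 0)
    p <- shortest_circular_path(fx$graph, fx$anchors)
    cn <- path_copy_numbers(fx$graph, p, fx$truth$base_abundance)
    called_multi <- cn$multi_copy[match(fx$truth$cycle_nodes, cn$node)]
    correct <- correct + sum(called_multi == (fx$truth$multiplicities >= 2))
    total <- total + length(mult)
  }
  expect_gte(correct / total, 0.95)
})

test_that("path validation requires pairs across every junction", {
  fx <- gen_assembly_fixture(915, plasmid_len = 9000, fraction_observed = 1,
                             n_anchor_nodes = 3)
  p <- shortest_circular_path(fx$graph, fx$anchors)
  expect_true(validate_path_with_pairs(fx$graph, p, fx$read_pairs))
  # drop all pairs spanning one junction
  seqs <- stats::setNames(fx$graph$nodes$seq, fx$graph$nodes$node_id)
  n2 <- fx$truth$cycle_nodes[2]
  keep <- !grepl("^$", fx$read_pairs$read1)
  drop <- vapply(seq_len(nrow(fx$read_pairs)), function(i) {
    m1 <- regexpr(fx$read_pairs$read1[i], seqs[[n2]], fixed = TRUE)[1] > 0
    m2 <- regexpr(fx$read_pairs$read2[i], seqs[[n2]], fixed = TRUE)[1] > 0
    m1 || m2
  }, logical(1))
  expect_false(validate_path_with_pairs(fx$graph, p, fx$read_pairs[!drop, ]))
})

test_that("completeness estimates follow the length-ratio contract", {
  est <- estimate_completeness("p", 8000, dtr_confirmed = TRUE)
  expect_equal(est$fraction, 1)
  expect_equal(est$method, "dtr_circular")
  expect_true(est$is_compls)

  none <- estimate_completeness("p", 8000, path = NULL)
  expect_equal(none$method, "none")
  expect_false(none$is_compls)

  # planted fractions recovered within 0.02; 0.55 is not a comPLS
  for (seed in 1:2) {
    for (f in c(0.5, 0.7, 0.9, 1.0)) {
      fx <- gen_assembly_fixture(920 + seed, plasmid_len = 9000,
                                 fraction_observed = f)
      p <- shortest_circular_path(fx$graph, fx$anchors)
      est <- estimate_completeness("p", nchar(fx$pls), path = p,
                                   anchor_nodes = fx$anchors, graph = fx$graph)
      expect_lt(abs(est$fraction - fx$truth$fraction), 0.02)
      expect_equal(est$is_compls, est$fraction > 0.6)
    }
  }

  # literal path-total reading stays available behind the switch
  fx <- gen_assembly_fixture(930, plasmid_len = 9000, fraction_observed = 1)
  p <- shortest_circular_path(fx$graph, fx$anchors)
  lit <- estimate_completeness("p", nchar(fx$pls), path = p,
                               anchor_nodes = fx$anchors, graph = fx$graph,
                               mode = "path_total")
  expect_equal(lit$fraction, 0.5, tolerance = 0.01)
})
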