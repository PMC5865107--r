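make_hits <- function(query_id, subject_id, bit_score) {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    percent_identity = 99, align_length = 500L, mismatches = 5L,
    gap_opens = 0L, q_start = 1L, q_end = 500L, s_start = 1L, s_end = 500L,
    e_value = 1e-50, bit_score = bit_score)
}

test_that("length filter is strictly greater-than at the boundary", {
  reads <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sequence = c(strrep("A", 451), strrep("A", 450), strrep("A", 460)))
  expect_message(kept <- length_filter(reads), "removed 1 of 3")
  expect_setequal(kept$read_id, c("a", "c"))
  expect_message(none <- length_filter(reads[0, ]), "removed 0 of 0")
  expect_equal(nrow(none), 0)
})

test_that("top-hit selection keeps top distinct score levels with all ties", {
  # 25 hits with 25 distinct scores -> the 20 best
  h <- make_hits(rep("q", 25), sprintf("r%02d", 1:25), seq(100, 1060, 40))
  kept <- select_top_hits(h, assignment_rule(top_k = 20))
  expect_equal(nrow(kept), 20)
  expect_equal(sort(kept$bit_score), sort(h$bit_score)[6:25])
  # 30 hits all with one score: a single distinct level, all retained
  h2 <- make_hits(rep("q", 30), sprintf("r%02d", 1:30), rep(700, 30))
  expect_equal(nrow(select_top_hits(h2, assignment_rule())), 30)
  # fewer hits than top_k: all retained
  h3 <- make_hits(rep("q", 3), c("r1", "r2", "r3"), c(1, 2, 3))
  expect_equal(nrow(select_top_hits(h3, assignment_rule())), 3)
  # ties at the boundary level are all retained
  h4 <- make_hits(rep("q", 5), sprintf("r%d", 1:5), c(900, 800, 700, 700, 600))
  kept4 <- select_top_hits(h4, assignment_rule(top_k = 3))
  expect_setequal(kept4$subject_id, c("r1", "r2", "r3", "r4"))
})

test_that("consensus applies species unanimity, the 60% genus rule, and various", {
  tax <- tibble::tibble(
    ref_id = sprintf("r%02d", 1:40),
    species = paste0("G", rep(1:10, each = 4), " sp", rep(1:4, 10)),
    genus = paste0("G", rep(1:10, each = 4)),
    tribe = NA_character_, family = "F")
  rule <- assignment_rule()
  # 20 hits all mapping to one species
  h <- make_hits(rep("q", 20), rep("r01", 20), 1000)
  a <- consensus_assign(h, tax, rule)
  expect_equal(a$rank, "species")
  expect_equal(a$label, "G1 sp1")
  expect_equal(a$n_hits_considered, 20L)
  # 12 of 20 hits (60%) in one genus -> genus (boundary is >=)
  h2 <- make_hits(rep("q", 20),
                  c(sprintf("r%02d", 1:4)[rep(1:3, 4)],  # 12 hits genus G1
                    sprintf("r%02d", seq(5, 33, 4))[1:8]),  # 8 other genera
                  1000)
  idx <- match(h2$subject_id, tax$ref_id)
  expect_equal(sum(tax$genus[idx] == "G1"), 12)
  a2 <- consensus_assign(h2, tax, rule)
  expect_equal(a2$rank, "genus")
  expect_equal(a2$label, "G1")
  # 11 of 20 (55%) -> various
  h3 <- make_hits(rep("q", 20),
                  c(rep(c("r01", "r02", "r03"), c(4, 4, 3)),  # 11 in G1
                    sprintf("r%02d", seq(5, 37, 4))[1:9]),
                  1000)
  a3 <- consensus_assign(h3, tax, rule)
  expect_equal(a3$rank, "various")
  expect_equal(a3$label, "various")
  # zero-hit reads become unknown
  a4 <- consensus_assign(h, tax, rule, query_ids = c("q", "q0"))
  expect_equal(a4$rank[a4$query_id == "q0"], "unknown")
  # unresolvable subject ids are a hard error
  expect_error(consensus_assign(make_hits("q", "rXX", 1), tax, rule),
               class = "pollinet_missing_taxonomy")
})

test_that("consensus is invariant to hit order", {
  tax <- toy_taxonomy()
  h <- make_hits(rep(c("q1", "q2"), each = 3),
                 c("r2", "r3", "r1", "r2", "r2", "r2"),
                 c(900, 900, 900, 800, 700, 600))
  a <- consensus_assign(h, tax, assignment_rule())
  set.seed(1)
  for (i in 1:5) {
    a2 <- consensus_assign(h[sample.int(nrow(h)), ], tax, assignment_rule())
    expect_identical(a, a2)
  }
})

test_that("curation resolves various by signature or query and logs an audit", {
  tax <- toy_taxonomy()
  asg <- tibble::tibble(
    query_id = c("q1", "q2", "q3", "q4"),
    label = c("various", "various", "Succisa pratensis", "various"),
    rank = c("various", "various", "species", "various"),
    n_hits_considered = c(5L, 5L, 20L, 4L),
    family_signature = c("Apiaceae", "Asteraceae|Ericaceae", "",
                         "Poaceae"))
  cur <- tibble::tibble(
    rule_type = c("signature", "query"),
    key = c("Apiaceae", "q2"),
    new_rank = c("family", "tribe"),
    new_label = c("Apiaceae", "Cardueae"))
  out <- apply_curation(asg, cur, tax)
  expect_equal(out$rank, c("family", "tribe", "species", "unknown"))
  expect_equal(out$label[1], "Apiaceae")
  expect_equal(out$label[2], "Cardueae")
  expect_equal(out$label[4], "unknown")
  audit <- attr(out, "audit")
  expect_equal(nrow(audit), 3)  # q3 passed through untouched
  expect_false("q3" %in% audit$query_id)
  bad <- cur
  bad$new_label[1] <- "Nosuchfamily"
  expect_error(apply_curation(asg, bad, tax), "Nosuchfamily")
})

test_that("tallying conserves reads per insect and ignores assignment order", {
  ins <- toy_insects()
  asg <- tibble::tibble(
    query_id = c("i1__r1", "i1__r2", "i1__r3", "i2__r1", "i3__r1"),
    label = c("Succisa pratensis", "Succisa pratensis", "unknown",
              "Cirsium", "Succisa pratensis"),
    rank = c("species", "species", "unknown", "genus", "species"),
    n_hits_considered = 1L, family_signature = "")
  tl <- tally_pollen(asg, ins)
  sums <- tapply(tl$count, tl$insect_id, sum)
  expect_equal(as.vector(sums[c("i1", "i2", "i3")]), c(3L, 1L, 1L))
  expect_equal(tl$count[tl$insect_id == "i1" & tl$taxon == "unknown"], 1L)
  set.seed(2)
  tl2 <- tally_pollen(asg[sample.int(nrow(asg)), ], ins)
  expect_identical(tl, tl2)
  # disjoint reads tally block-diagonally: i1 never gains i2's taxa
  expect_equal(nrow(tl[tl$insect_id == "i1" & tl$taxon == "Cirsium", ]), 0)
  bad <- asg
  bad$query_id[1] <- "iX__r1"
  expect_error(tally_pollen(bad, ins), "iX")
})

test_that("every length-passing read receives exactly one rank (partition)", {
  sim <- simulate_pollen_study(tiny_sim_config(seed = 8,
                                               reads_per_individual = 15L))
  rule <- assignment_rule(min_length = 250L)
  kept <- suppressMessages(length_filter(sim$reads, 250L))
  top <- select_top_hits(sim$hits, rule)
  asg <- consensus_assign(top, sim$refdb$taxonomy, rule,
                          query_ids = kept$read_id)
  asg <- apply_curation(asg, tibble::tibble(
    rule_type = character(), key = character(), new_rank = character(),
    new_label = character()), sim$refdb$taxonomy)
  expect_setequal(asg$query_id, kept$read_id)
  expect_equal(anyDuplicated(asg$query_id), 0L)
  expect_true(all(asg$rank %in% c("species", "genus", "family", "tribe",
                                  "unknown")))
})
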