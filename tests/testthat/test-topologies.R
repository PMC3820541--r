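test_that("the 32 topologies form a bijection between ids and codes", {
  tab <- relay_topologies()
  expect_equal(nrow(tab), 32L)
  expect_equal(tab$id, 1:32)
  code <- paste(tab$r2, tab$r3, tab$r4, tab$h1, tab$h2)
  expect_equal(anyDuplicated(code), 0L)
  # published id <-> code pairings
  expect_equal(unlist(relay_topology(14)[c("r2", "r3", "r4", "h1", "h2")]),
               c(r2 = 0L, r3 = 1L, r4 = 1L, h1 = 1L, h2 = 0L))
  expect_equal(unlist(relay_topology(25)[c("r2", "r3", "r4", "h1", "h2")]),
               c(r2 = 1L, r3 = 0L, r4 = 0L, h1 = 1L, h2 = 1L))
  expect_equal(unlist(relay_topology(30)[c("r2", "r3", "r4", "h1", "h2")]),
               c(r2 = 0L, r3 = 1L, r4 = 1L, h1 = 1L, h2 = 1L))
  # code lookup inverts id lookup
  for (id in c(1L, 8L, 14L, 19L, 25L, 32L)) {
    t1 <- relay_topology(id)
    t2 <- relay_topology(rev = c(t1$r2, t1$r3, t1$r4), hyd = c(t1$h1, t1$h2))
    expect_equal(t2$id, id)
  }
  expect_error(relay_topology(33), "1..32")
})

test_that("responsiveness predicate partitions 32 topologies into 14 + 18", {
  tab <- relay_topologies()
  nonresp <- tab$h2 == 0L & (tab$h1 == 0L | tab$r3 == 0L | tab$r4 == 0L)
  expect_equal(sum(nonresp), 14L)
  expect_equal(tab$responsive, !nonresp)
  expect_true(is_responsive(30))
  expect_false(is_responsive(relay_topology(rev = c(1, 1, 1),
                                            hyd = c(0, 0))))
})
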