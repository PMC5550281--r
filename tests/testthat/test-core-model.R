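test_that("polyadic counting: one site with three partners is three synapses", {
  s <- site_row("s1", "KC-ab-s.1", 100, 100, 100, "a3")
  cc <- data.frame(site_id = "s1",
                   post_neuron = c("MBON-a3.A", "KC-ab-c-i.1", "APL.1"))
  x <- build_connectome(s, cc)
  expect_equal(nrow(x$sites), 1L)
  expect_equal(n_synapses(x), 3L)
})

test_that("reader handles empty contact tables and round-trips its own output", {
  td <- withr::local_tempdir()
  sf <- file.path(td, "sites.csv"); cf <- file.path(td, "contacts.csv")
  af <- file.path(td, "ann.csv")

  writeLines("site_id,pre_neuron,x,y,z,compartment", sf)
  writeLines("site_id,post_neuron", cf)
  writeLines(c("neuron_id,cell_type,instance_label", "k1,KC-ab-s,"), af)
  x0 <- read_synapse_table(sf, cf, af, quiet = TRUE)
  expect_equal(n_synapses(x0), 0L)
  expect_equal(nrow(x0$sites), 0L)

  gen <- generate_connectome(small_config(seed = 7L, n_s = 10L))
  x <- gen$connectome
  write_synapse_table(x, sf, cf, af)
  y <- read_synapse_table(sf, cf, af, quiet = TRUE)
  expect_equal(y$sites, x$sites)
  expect_equal(y$contacts, x$contacts)
  expect_equal(y$neurons$cell_type, x$neurons$cell_type)
})

test_that("referential and schema violations are hard errors naming the problem", {
  s <- site_row("s1", "KC-ab-s.1", 0, 0, 0)
  ok <- data.frame(site_id = "s1", post_neuron = "KC-ab-s.1")
  neurons <- data.frame(neuron_id = "KC-ab-s.1", cell_type = "KC-ab-s")

  expect_error(connectome(neurons, s,
                          data.frame(site_id = "nope", post_neuron = "KC-ab-s.1")),
               "unknown site_id")
  expect_error(connectome(neurons, s,
                          data.frame(site_id = "s1", post_neuron = "ghost")),
               "unknown postsynaptic neuron")
  expect_error(connectome(neurons, s, rbind(ok, ok)), "duplicate")
  expect_error(connectome(data.frame(neuron_id = "n1", cell_type = "not-a-type"),
                          s[0, ], ok[0, ]),
               "valid tokens")
  s_bad <- s; s_bad$x <- -5
  expect_error(connectome(neurons, s_bad, ok), "negative coordinate")
  s_na <- s; s_na$z <- NA_real_
  expect_error(connectome(neurons, s_na, ok), "malformed coordinate")
})

test_that("edge export conserves the contact count under any grouping", {
  gen <- generate_connectome(small_config(
    seed = 11L, n_s = 15L,
    extra_wiring = data.frame(pre_type = "KC-ab-s", post_type = "PPL1-a3",
                              compartment = "a3", lambda = 1),
    extra_extrinsic = data.frame(cell_type = "PPL1-a3", compartment = "a3",
                                 n = 2L)))
  x <- gen$connectome

  for (grp in c("neuron", "cell_type")) {
    ed <- export_edges(x, grp)
    expect_equal(sum(ed$n_synapses), n_synapses(x))
  }

  # independent tally: join contacts to sites by hand and count one pair
  ct <- merge(x$contacts, x$sites, by = "site_id")
  pick_pre <- x$sites$pre_neuron[1]
  pick_post <- ct$post_neuron[ct$pre_neuron == pick_pre][1]
  manual <- sum(ct$pre_neuron == pick_pre & ct$post_neuron == pick_post)
  ed <- export_edges(x, "neuron")
  got <- ed$n_synapses[ed$pre == pick_pre & ed$post == pick_post]
  expect_equal(sum(got), manual)

  # all cells of one type collapse to a single row per (post type, compartment)
  ed_t <- export_edges(x, "cell_type")
  expect_true(all(table(ed_t$pre, ed_t$post, ed_t$compartment) <= 1))
})

test_that("partition conservation: per-class synapse counts sum to the total", {
  gen <- generate_connectome(small_config(
    seed = 3L, n_s = 12L,
    extra_wiring = data.frame(pre_type = "PPL1-a3", post_type = "KC",
                              compartment = "a3", lambda = 0.5),
    extra_extrinsic = data.frame(cell_type = "PPL1-a3", compartment = "a3",
                                 n = 2L)))
  x <- gen$connectome
  ct <- merge(x$contacts, x$sites, by = "site_id")
  cls <- x$neurons$type_class[match(ct$pre_neuron, x$neurons$neuron_id)]
  expect_equal(sum(table(cls)), n_synapses(x))
})

test_that("SWC reading validates tree structure", {
  td <- withr::local_tempdir()
  f <- file.path(td, "skel.swc")

  writeLines(c("# comment",
               "1 0 0 0 0 1 -1",
               "2 0 1000 0 0 1 1",
               "3 0 1000 2000 0 1 2"), f)
  sk <- read_skeleton(f)
  expect_s3_class(sk, "skeleton")
  expect_equal(nrow(sk$nodes), 3L)
  expect_equal(sk$root_id, "1")
  expect_equal(cable_length(sk), 3, tolerance = 1e-12)

  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 -1"), f)
  expect_error(read_skeleton(f), "exactly one root")

  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 99"), f)
  expect_error(read_skeleton(f), "absent parent")

  # two nodes pointing at each other are unreachable from the root
  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 3", "3 0 2 0 0 1 2"), f)
  expect_error(read_skeleton(f), "not a connected tree")
})

test_that("cable length is invariant under node re-indexing", {
  set.seed(42)
  n <- 30L
  parent <- c(NA, sample(seq_len(n - 1L), n - 1L, replace = TRUE))
  parent <- ifelse(is.na(parent), NA, pmin(parent, seq_len(n) - 1L))
  nodes <- data.frame(node_id = as.character(seq_len(n)),
                      x = runif(n, 0, 1e4), y = runif(n, 0, 1e4),
                      z = runif(n, 0, 1e4),
                      parent = as.character(parent))
  sk1 <- skeleton(nodes)
  perm <- sample.int(n)
  relab <- setNames(sprintf("n%02d", seq_len(n)), nodes$node_id)
  nodes2 <- nodes[perm, ]
  nodes2$node_id <- unname(relab[nodes2$node_id])
  nodes2$parent <- ifelse(is.na(nodes2$parent), NA,
                          unname(relab[nodes2$parent]))
  sk2 <- skeleton(nodes2)
  expect_equal(cable_length(sk1), cable_length(sk2), tolerance = 1e-12)
})
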