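test_that("per-cell counts include explicit zeros and match a hand tally", {
  s <- rbind(site_row("s1", "KC-ab-s.1", 0, 0, 0, "a3"),
             site_row("s2", "KC-ab-s.1", 50, 0, 0, "a3"))
  cc <- data.frame(site_id = c("s1", "s2"), post_neuron = "MBON-a3.A")
  x <- build_connectome(rbind(s, site_row("s3", "KC-ab-s.2", 900, 0, 0, "a3")),
                        rbind(cc, data.frame(site_id = "s3",
                                             post_neuron = "KC-ab-s.1")))
  cnt <- per_cell_counts(x, "KC", "MBON-a3.A")
  expect_equal(unname(cnt[c("KC-ab-s.1", "KC-ab-s.2")]), c(2L, 0L))
  expect_error(per_cell_counts(x, character(0), "MBON-a3.A"))

  gen <- generate_connectome(small_config(seed = 31L, n_s = 30L, lambda = 3))
  xg <- gen$connectome
  mbon <- xg$neurons$neuron_id[xg$neurons$type_class == "MBON"][1]
  cnt <- per_cell_counts(xg, "KC", mbon)
  ct <- merge(xg$contacts, xg$sites, by = "site_id")
  manual <- table(factor(ct$pre_neuron[ct$post_neuron == mbon],
                         levels = names(cnt)))
  expect_equal(unname(cnt), unname(as.integer(manual)))
})

test_that("wiring summary reproduces the printed-table derivations", {
  # the published derivation: mean per connected KC = total / connected
  t2 <- printed_table("kc_mbon")
  sc <- t2[t2$post_mbon == "MBON-a2sc", ]
  expect_equal(round(mean_per_connected(sc$total_synapses, sc$n_pre_kc), 2),
               12.41)

  gen <- generate_connectome(small_config(seed = 17L, n_s = 40L, lambda = 4))
  x <- gen$connectome
  mbon <- x$neurons$neuron_id[x$neurons$type_class == "MBON"][1]
  ws <- wiring_summary(x, "KC", mbon)
  cnt <- per_cell_counts(x, "KC", mbon)
  expect_equal(ws$total_synapses, sum(cnt))
  expect_equal(ws$n_pre_connected, sum(cnt > 0))
  expect_equal(ws$mean_per_connected_pre * ws$n_pre_connected,
               ws$total_synapses)
  b <- ws$subtype_breakdown
  expect_equal(sum(b$n_synapses), ws$total_synapses)
  expect_lt(abs(sum(b$percent, na.rm = TRUE) - 100), 0.1)
})

test_that("sampling profile recombines to the cell's total input", {
  gen <- generate_connectome(generator_config(
    n_kc = c("KC-ab-s" = 25L, "KC-ab-p" = 10L),
    extrinsic = data.frame(cell_type = "MBON-a3", compartment = "a3", n = 1L),
    wiring = data.frame(pre_type = c("KC-ab-s", "KC-ab-p"),
                        post_type = "MBON-a3", compartment = "a3",
                        lambda = c(4, 0.8)),
    seed = 5L))
  x <- gen$connectome
  sp <- sampling_profile(x, "MBON-a3.A")
  expect_true(all(sp$connected <= sp$available))
  expect_true(all(sp$mean_connected[sp$connected > 0] >= 1))
  total <- wiring_summary(x, "KC", "MBON-a3.A")$total_synapses
  expect_equal(recombine_sampling(sp), total)

  # published cross-consistency: Table-3 row recombines to the Table-2
  # total within the rounding of the printed means
  t3 <- printed_table("kc_mbon_sampling")
  t2 <- printed_table("kc_mbon")
  rec <- recombine_sampling(t3[t3$post_mbon == "MBON-a3-A", ])
  expect_lt(abs(rec - t2$total_synapses[t2$post_mbon == "MBON-a3-A"]), 1)
})

test_that("compartment additivity: totals over compartments sum to the lobe total", {
  wiring <- data.frame(pre_type = "KC-ab-s",
                       post_type = c("MBON-a3", "MBON-a1"),
                       compartment = c("a3", "a1"), lambda = c(2, 3))
  extr <- data.frame(cell_type = c("MBON-a3", "MBON-a1"),
                     compartment = c("a3", "a1"), n = 1L)
  gen <- generate_connectome(generator_config(
    n_kc = c("KC-ab-s" = 20L), extrinsic = extr, wiring = wiring,
    convergence_rate = 0, rosette_rate = 0, seed = 8L))
  x <- gen$connectome
  tot <- vapply(c("a1", "a2", "a3"), function(cc)
    sum(vapply(x$neurons$neuron_id[x$neurons$type_class == "MBON"],
               function(m) {
                 w <- wiring_summary(x, "KC", m, compartment = cc)
                 w$total_synapses
               }, numeric(1))), numeric(1))
  expect_equal(sum(tot), n_synapses(x))
})

test_that("type matrix conserves counts and ignores neuron identities", {
  gen <- generate_connectome(small_config(
    seed = 23L, n_s = 15L,
    extra_wiring = data.frame(pre_type = "PPL1-a3", post_type = "KC",
                              compartment = "a3", lambda = 0.4),
    extra_extrinsic = data.frame(cell_type = "PPL1-a3", compartment = "a3",
                                 n = 2L)))
  x <- gen$connectome
  tm <- type_matrix(x)
  expect_equal(sum(tm$all), n_synapses(x))
  expect_equal(Reduce(`+`, tm[names(tm) != "all"]), tm$all)

  # independent tally of one cell
  ct <- merge(x$contacts, x$sites, by = "site_id")
  tt <- x$neurons$cell_type[match(ct$pre_neuron, x$neurons$neuron_id)]
  pt <- x$neurons$cell_type[match(ct$post_neuron, x$neurons$neuron_id)]
  expect_equal(tm$all["KC-ab-s", "MBON-a3"],
               sum(tt == "KC-ab-s" & pt == "MBON-a3"))

  # permuting neuron ids leaves the matrix unchanged
  set.seed(1)
  ids <- x$neurons$neuron_id
  relab <- setNames(paste0("cell", sample(seq_along(ids))), ids)
  y <- connectome(
    transform(x$neurons, neuron_id = unname(relab[neuron_id])),
    transform(x$sites, pre_neuron = unname(relab[pre_neuron])),
    transform(x$contacts, post_neuron = unname(relab[post_neuron])))
  expect_equal(type_matrix(y)$all, tm$all)
})

test_that("single-type grouping collapses the edge list to one row", {
  s <- rbind(site_row("s1", "KC-ab-s.1", 0, 0, 0),
             site_row("s2", "KC-ab-s.2", 500, 0, 0))
  cc <- data.frame(site_id = c("s1", "s2"),
                   post_neuron = c("KC-ab-s.2", "KC-ab-s.1"))
  x <- build_connectome(s, cc)
  ed <- export_edges(x, "cell_type")
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$n_synapses, 2L)
})
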