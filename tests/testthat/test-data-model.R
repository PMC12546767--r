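test_that("ingest groups rows by assay and populates registries", {
  col <- ingest_assays(toy_assay_table())
  expect_s3_class(col, "assay_collection")
  expect_equal(nrow(col$assays), 2)
  expect_equal(col$assays$n_ligands, c(2L, 2L))
  expect_setequal(col$ligand_registry$ligand_id, c("l1", "l2", "l3", "l4"))
  expect_true(all(lengths(col$assays$pocket_ids) >= 1))
})

test_that("ingest rejects malformed tables with informative errors", {
  tbl <- toy_assay_table()
  expect_error(ingest_assays(tbl[, -4]), class = "ligspace_schema_error")
  expect_error(ingest_assays(tbl[0, ]), class = "ligspace_schema_error")

  mixed <- tbl
  mixed$unit[2] <- "%"
  err <- expect_error(ingest_assays(mixed), class = "ligspace_validation_error")
  expect_match(conditionMessage(err), "A1")

  dup <- dplyr::bind_rows(tbl, tbl[1, ])
  err <- expect_error(ingest_assays(dup), class = "ligspace_validation_error")
  expect_match(conditionMessage(err), "A1/l1")

  neg <- tbl
  neg$value[1] <- -2
  expect_error(ingest_assays(neg), class = "ligspace_validation_error")
})

test_that("qualified-relation rows are dropped with a warning", {
  tbl <- toy_assay_table()
  tbl$relation <- c("=", "<", "", ">")
  expect_warning(col <- ingest_assays(tbl), "qualified")
  expect_equal(nrow(col$measurements), 2)
  expect_false("relation" %in% names(col$measurements))
})

test_that("to_potency maps units to the canonical p-scale", {
  out <- to_potency(c(1, 10), c("nM", "uM"))
  expect_equal(out$potency, c(9, 5))
  expect_equal(out$scale, c("molar", "molar"))

  pct <- to_potency(55, "%")
  expect_equal(pct$potency, 55)  # ordering value retained
  expect_equal(pct$scale, "rank_only")

  dens <- to_potency(1000, "ug/mL")  # 1 g/L
  expect_equal(dens$potency, 0)
  expect_equal(dens$scale, "density")

  expect_error(to_potency(-1, "nM"), class = "ligspace_domain_error")
  expect_error(to_potency(0, "uM"), class = "ligspace_domain_error")
  expect_error(to_potency(1, "furlong"), class = "ligspace_validation_error")
})

test_that("activity labels follow the inclusive 10 uM molar boundary", {
  tbl <- tibble::tibble(
    assay_id = c("A1", "A1", "A2", "A3"),
    target_group_id = c("T1", "T1", "T2", "T3"),
    ligand_id = c("l1", "l2", "l3", "l4"),
    value = c(5, 10, 20, 60),
    unit = c("uM", "uM", "uM", "%"))
  lab <- label_activity(ingest_assays(tbl))
  get <- function(lig) lab$label[lab$ligand_id == lig]
  expect_equal(get("l1"), "active")
  expect_equal(get("l2"), "active")    # boundary inclusive
  expect_equal(get("l3"), "inactive")
  expect_equal(get("l4"), "unlabeled") # percent never labels
})

test_that("labels are independent of assay membership", {
  # the same target-ligand measurement split across different assays
  tbl1 <- tibble::tibble(assay_id = "A1", target_group_id = "T1",
                         ligand_id = "l1", value = 3, unit = "uM")
  tbl2 <- tibble::tibble(assay_id = c("B1", "B2"),
                         target_group_id = c("T1", "T9"),
                         ligand_id = c("l1", "zz"),
                         value = c(3, 1), unit = "uM")
  l1 <- label_activity(ingest_assays(tbl1))
  l2 <- label_activity(ingest_assays(tbl2))
  expect_equal(l1$label[l1$ligand_id == "l1"],
               l2$label[l2$ligand_id == "l1"])
  # idempotence
  expect_identical(label_activity(ingest_assays(tbl2)), l2)
})

test_that("density units rank within assay but never label activity", {
  tbl <- tibble::tibble(assay_id = "A1", target_group_id = "T1",
                        ligand_id = c("l1", "l2"), value = c(1, 100),
                        unit = "ug/mL")
  col <- ingest_assays(tbl)
  expect_true(all(label_activity(col)$label == "unlabeled"))
  r <- rank_ligands(col, assay_id = "A1")
  expect_equal(r$ligand_id, c("l1", "l2"))  # lower mass conc = stronger
})

test_that("rank_ligands orders best-first with stable tie groups", {
  a <- tibble::tibble(ligand_id = c("l4", "l2", "l3", "l1"),
                      value = 10^(9 - c(5, 7, 7, 9)), unit = "nM")
  r <- rank_ligands(a)
  expect_equal(r$ligand_id, c("l1", "l2", "l3", "l4"))
  expect_equal(r$tie_group, c(1, 2, 2, 3))

  single <- rank_ligands(tibble::tibble(ligand_id = "x", value = 1,
                                        unit = "nM"))
  expect_equal(nrow(single), 1)
  expect_equal(single$rank, 1L)

  pct <- rank_ligands(tibble::tibble(ligand_id = c("l1", "l2", "l3"),
                                     value = c(80, 20, 50), unit = "%"))
  expect_equal(pct$ligand_id, c("l1", "l3", "l2"))
  expect_equal(pct$scale, rep("rank_only", 3))
})

test_that("within-assay ordering is invariant under monotone value maps", {
  # percent readouts order by reported value, so any strictly increasing
  # transform of the values must preserve the ranking
  vals <- c(17, 80, 42, 63, 5)
  a1 <- tibble::tibble(ligand_id = paste0("l", 1:5), value = vals, unit = "%")
  a2 <- a1
  a2$value <- exp(vals / 20)  # strictly increasing transform
  expect_equal(rank_ligands(a1)$ligand_id, rank_ligands(a2)$ligand_id)
})

test_that("collection round-trips through CSV identically", {
  w <- tiny_world()
  col <- sample_assays(w, 5, 8, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_collection(col, path)
  back <- read_assay_collection(path)
  expect_equal(back$measurements, col$measurements)
  expect_equal(back$assays, col$assays)
})
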