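test_that("the packaged survey fixture loads with the published totals", {
  ds <- fixture_dataset()
  expect_s3_class(ds, "occurrence_dataset")
  expect_equal(nrow(ds$hosts), 144)
  expect_equal(nrow(ds$records), 365)
  expect_equal(nrow(ds$taxa), 29)
  expect_equal(sum(ds$records$abundance), 1246)
  n_with <- length(unique(ds$records$host_id))
  expect_equal(n_with, 139)
  expect_equal(nrow(ds$hosts) - n_with, 5)
})

test_that("an empty records file with a roster yields symbiont-free hosts", {
  occ <- write_tsv_tmp(data.frame(host_id = character(),
                                  host_species = character(),
                                  source = character(), taxon = character(),
                                  genus = character(), family = character(),
                                  ecological_group = character(),
                                  abundance = integer()))
  roster <- write_tsv_tmp(data.frame(id = c("h1", "h2", "h3"),
                                     species = "Molothrus bonariensis"))
  ds <- read_occurrence_table(occ, roster)
  expect_equal(nrow(ds$hosts), 3)
  expect_equal(nrow(ds$records), 0)
})

test_that("schema, abundance and referential violations raise classed errors", {
  roster <- write_tsv_tmp(data.frame(id = "h1",
                                     species = "Molothrus bonariensis"))
  base_row <- data.frame(host_id = "h1",
                         host_species = "Molothrus bonariensis",
                         source = "wild_capture", taxon = "t1", genus = "G",
                         family = "F", ecological_group = "vane",
                         abundance = 2, stringsAsFactors = FALSE)

  ## duplicate (host, taxon) rows are an error, never merged
  dup <- write_tsv_tmp(rbind(base_row, base_row))
  expect_error(read_occurrence_table(dup, roster),
               class = "hostspec_referential_error")

  ## missing column
  nocol <- write_tsv_tmp(base_row[, setdiff(names(base_row), "abundance")])
  expect_error(read_occurrence_table(nocol, roster),
               class = "hostspec_schema_error")

  ## abundance below one
  zero <- base_row; zero$abundance <- 0
  expect_error(read_occurrence_table(write_tsv_tmp(zero), roster),
               class = "hostspec_validation_error")

  ## host absent from the roster
  orphan <- base_row; orphan$host_id <- "h9"
  expect_error(read_occurrence_table(write_tsv_tmp(orphan), roster),
               class = "hostspec_referential_error")

  ## quill/skin taxa can never be 'specific'
  expect_error(occurrence_dataset(
    data.frame(id = "h1", species = "x"),
    data.frame(name = "t", genus = "G", family = "F",
               ecological_group = "quill_skin", category = "specific"),
    data.frame()), class = "hostspec_validation_error")
})

test_that("record and abundance totals are conserved across per-taxon sums", {
  for (seed in 1:5) {
    sim <- simulate_transmission(transmission_sim_config(
      40, 4, 2, 3, q_vi = 0.3, q_hc = 0.1, q_hi = 0.05,
      n_contacts_conspecific = 5, n_contacts_interspecific = 4, seed = seed))
    ds <- sim$dataset
    per_taxon <- table(ds$records$taxon)
    expect_equal(sum(per_taxon), nrow(ds$records))
    expect_equal(sum(tapply(ds$records$abundance, ds$records$taxon, sum)),
                 sum(ds$records$abundance))
  }
})

test_that("occurrence write/read round-trips are lossless", {
  ds <- fixture_dataset()
  f1 <- tempfile(); f2 <- tempfile()
  write_occurrence_table(ds, f1, f2)
  ds2 <- read_occurrence_table(f1, f2)
  expect_equal(nrow(ds2$records), nrow(ds$records))
  key <- function(d) {
    r <- d$records[order(d$records$host_id, d$records$taxon), ]
    rownames(r) <- NULL
    r
  }
  expect_equal(key(ds2), key(ds))
  expect_equal(sort(ds2$taxa$name), sort(ds$taxa$name))
  expect_equal(ds2$taxa$category[order(ds2$taxa$name)],
               ds$taxa$category[order(ds$taxa$name)])
  ## deterministic writer: rewriting gives identical bytes
  f3 <- tempfile()
  write_occurrence_table(ds2, f3)
  expect_identical(readLines(f1), readLines(f3))
})
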