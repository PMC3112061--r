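# Parsing and round-tripping of the plain-text dialects.

toy_layout <- function() {
  plate_layout(data.frame(
    well = c("A1", "A2", "NTC1"),
    sample_id = c("S1", "S1", "NTC"),
    material = c("gDNA", "gDNA", "NTC"),
    replicate = c(1L, 2L, 1L),
    marker_snp = "snp1"), expected_replicates = 2L)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("a small wide melt table parses into annotated curves", {
  path <- write_lines_tmp(c("Temperature,A1,A2",
                            "35.0,10,20", "35.1,11,21", "35.2,12,22"))
  curves <- read_melt_table(path, toy_layout())
  expect_length(curves, 2L)
  expect_equal(curves[[1]]$well_id, "A1")
  expect_equal(curves[[1]]$sample_id, "S1")
  expect_equal(curves[[1]]$material, "gDNA")
  expect_equal(curves[[2]]$fluorescence, c(20, 21, 22))
  expect_equal(curves[[1]]$temperatures, c(35.0, 35.1, 35.2))
})

test_that("descending temperature exports are re-sorted consistently", {
  path <- write_lines_tmp(c("Temperature,A1", "36.0,30", "35.5,20", "35.0,10"))
  cu <- read_melt_table(path, toy_layout())[[1]]
  expect_equal(cu$temperatures, c(35.0, 35.5, 36.0))
  expect_equal(cu$fluorescence, c(10, 20, 30))
})

test_that("tab-delimited tables are auto-detected", {
  path <- write_lines_tmp(c("Temperature\tA1", "35.0\t1", "35.1\t2", "35.2\t3"),
                          ext = ".tsv")
  expect_equal(read_melt_table(path, toy_layout())[[1]]$fluorescence, 1:3 * 1.0)
})

test_that("unknown wells, ragged rows and non-monotone grids are hard errors", {
  bad_well <- write_lines_tmp(c("Temperature,Z9", "35.0,1", "35.1,2"))
  expect_error(read_melt_table(bad_well, toy_layout()), "Z9")
  ragged <- write_lines_tmp(c("Temperature,A1,A2", "35.0,1,2", "35.1,3"))
  expect_error(read_melt_table(ragged, toy_layout()), "ragged|missing")
  dup_t <- write_lines_tmp(c("Temperature,A1", "35.0,1", "35.0,2", "35.1,3"))
  expect_error(read_melt_table(dup_t, toy_layout()), "monotone")
  not_temp <- write_lines_tmp(c("Degrees,A1", "35.0,1", "35.1,2"))
  expect_error(read_melt_table(not_temp, toy_layout()), "Temperature")
})

test_that("a full 96-well sample sheet (8 LCLs x 3 materials x 4 reps) validates", {
  rows <- expand.grid(rep = 1:4, material = c("gDNA", "cDNA", "cDNA_puromycin"),
                      sample = sprintf("LCL%02d", 1:8), stringsAsFactors = FALSE)
  df <- data.frame(well = paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8)),
                   sample_id = rows$sample, material = rows$material,
                   replicate = rows$rep, marker_snp = "snp1")
  df <- rbind(df, data.frame(well = "NTC1", sample_id = "NTC", material = "NTC",
                             replicate = 1, marker_snp = "snp1"))
  path <- write_lines_tmp(c("well,sample_id,material,replicate,marker_snp",
                            apply(df, 1, paste, collapse = ",")))
  layout <- read_sample_sheet(path)
  expect_s3_class(layout, "plate_layout")
  expect_equal(nrow(layout), 97L)
  expect_equal(sum(layout$material != "NTC"), 96L)
  expect_equal(attr(layout, "ntc_wells"), "NTC1")
})

test_that("material aliases parse case-insensitively and bad tokens error", {
  expect_equal(meltDAE:::parse_material(c("gdna", "CDNA", "cdna_puro",
                                          "Puromycin", "ntc")),
               c("gDNA", "cDNA", "cDNA_puromycin", "cDNA_puromycin", "NTC"))
  expect_error(meltDAE:::parse_material("mystery"), "mystery")
})

test_that("duplicate wells error; zero NTC wells only warn", {
  base <- data.frame(well = c("A1", "A1"), sample_id = "S1", material = "gDNA",
                     replicate = 1:2, marker_snp = "snp1")
  expect_error(plate_layout(base), "duplicate")
  no_ntc <- data.frame(well = c("A1", "A2"), sample_id = "S1", material = "gDNA",
                       replicate = 1:2, marker_snp = "snp1")
  expect_warning(plate_layout(no_ntc, expected_replicates = 2L), "NTC")
})

test_that("non-default replicate counts warn but are accepted", {
  df <- data.frame(well = c("A1", "A2", "A3", "N1"),
                   sample_id = c("S1", "S1", "S1", "NTC"),
                   material = c("gDNA", "gDNA", "gDNA", "NTC"),
                   replicate = c(1:3, 1), marker_snp = "snp1")
  expect_warning(plate_layout(df), "replicates")
})

test_that("results tables round-trip losslessly to 1e-6", {
  res1 <- dae_test(gdna = c(0.80, 0.82, 0.78, 0.80),
                   cdna = c(0.40, 0.41, 0.39, 0.40),
                   puromycin = c(0.79, 0.81, 0.80, 0.78),
                   sample_id = "S1", marker_snp = "snp1")
  res2 <- dae_test(gdna = c(1.01, 0.99, 1.02, 0.98),
                   cdna = c(1.00, 1.03, 0.97, 1.01),
                   sample_id = "S2", marker_snp = "snp1")
  path <- tempfile(fileext = ".tsv")
  write_results_table(list(res1, res2), path, header = "round-trip test")
  back <- read_results_table(path)
  expect_equal(nrow(back), 2L)
  orig <- do.call(rbind, lapply(list(res1, res2), as.data.frame))
  for (col in c("mean_log_gdna", "mean_log_cdna", "mean_log_puro", "delta",
                "dae_percent", "ci_low", "ci_high", "t_stat", "p_value")) {
    expect_equal(back[[col]], orig[[col]], tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(back$call, orig$call)
  expect_equal(back$nmd_class, orig$nmd_class)
})

test_that("writing an empty result set errors", {
  expect_error(write_results_table(list(), tempfile()), "no results")
})

test_that("assay configs read from YAML and JSON equivalently", {
  y <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(markers = list(snp1 = list(allele1_window = c(50, 57),
                                                   allele2_window = c(57.5, 64))),
                        sg_window = 11, sg_order = 3, alpha = 0.01), y)
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(markers = list(snp1 = list(allele1_window = c(50, 57),
                                                       allele2_window = c(57.5, 64))),
                            sg_window = 11, sg_order = 3, alpha = 0.01), j,
                       auto_unbox = TRUE)
  cy <- read_assay_config(y)
  cj <- read_assay_config(j)
  expect_equal(cy$alpha, 0.01)
  expect_equal(cy$sg_window, cj$sg_window)
  expect_equal(cy$markers$snp1$allele1_window, cj$markers$snp1$allele1_window)
})

test_that("assay config invariants are enforced", {
  expect_error(assay_config(sg_window = 10), "odd")
  expect_error(assay_config(sg_window = 5, sg_order = 5), "smaller")
  expect_error(assay_config(alpha = 1.2), "alpha")
  expect_error(assay_config(markers = list(s = list(allele1_window = c(50, 60),
                                                    allele2_window = c(58, 64)))),
               "below")
})
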