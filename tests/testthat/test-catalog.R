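# The rule catalog: transcription fidelity, parsing, canonicalization.

table_rows <- list(
  Ash = c("II-1A" = "AWS-SET",
          "II-1B" = "AWS-SET-PostSET",
          "II-2A" = "PHD-PHD-PHD-AWS-SET",
          "II-2B" = "PHD-AWS-SET",
          "II-3A" = "ZnF_C2H2-AWS-SET-PostSET",
          "II-3B" = "ZnF_C2H2-AWS-SET",
          "II-3C" = "ZnF_C2H2-AWS-SET-ZnF_C2H2-ZnF_C2H2",
          "II-Orphan" = "SET"),
  Trx = c("III-1A" = "PWWP-FYR-PHD-PHD-SET",
          "III-1B" = "PWWP-FYR-PHD-SET",
          "III-1C" = "FYR-PHD-PHD-SET",
          "III-1D" = "ZnF_C2H2-PHD-PHD-PHD-PHD-PHD-FYR-SET-PostSET",
          "III-1E" = "PWWP-FYR-PHD-PHD-SET-PostSET",
          "III-2A" = "PWWP-PHD-PHD-PHD-SET",
          "III-2B" = "PWWP-PHD-PHD-PHD-SET-PostSET",
          "III-2C" = "PWWP-PHD-HMGb-SAND-PHD-PHD-ZnF_C2H2-SET-PostSET",
          "III-2D" = "PWWP-AWS-SET",
          "III-3A" = "PHD-PHD-SET",
          "III-3B" = "PHD-PHD-SET-PostSET",
          "III-3C" = "PHD-SET",
          "III-3D" = "PHD-PreSET-SET",
          "III-3E" = "PHD-SET-PostSET",
          "III-3F" = "PHD-HMG-SET",
          "III-4A" = "ZnF_C2H2-GYF-HMGCOA-SET-PostSET",
          "III-4B" = "SET-PostSET",
          "III-Orphan" = "SET"),
  "Su(var)" = c("IV-1A" = "SRA-PreSET-SET",
                "IV-1B" = "SRA-SET",
                "IV-1C" = "SRA-PreSET-SET-SET",
                "IV-2A" = "PreSET-SET",
                "IV-2B" = "PHD-PreSET-SET",
                "IV-2C" = "ZnF_C2H2-ZnF_C2H2-PreSET-SET-PostSET",
                "IV-2D" = "WIYLD-PreSET-SET",
                "IV-2E" = "PreSET-SET-PostSET",
                "IV-2F" = "ZnF-PreSET-SET",
                "IV-2G" = "PreSET-AWS-SET",
                "IV-Orphan" = "SET"))

test_that("shipped catalog reproduces the family tables row for row", {
  cat_ <- default_catalog()
  df <- as.data.frame(cat_)
  for (fam in names(table_rows)) {
    rows <- df[df$family == fam, ]
    expect_equal(rows$id, names(table_rows[[fam]]))
    expect_equal(setNames(rows$backbone, rows$id), table_rows[[fam]])
  }
  # seven E(z) architecture variants, all distinct, all SET-bearing
  ez <- df[df$family == "E(z)", ]
  expect_equal(nrow(ez), 7)
  expect_false(anyDuplicated(ez$backbone) > 0)
  expect_true(all(grepl("SET", ez$backbone)))
})

test_that("presence strings are 16-wide and match transcribed rows", {
  cat_ <- default_catalog()
  expect_true(all(vapply(cat_, function(e) length(e$presence), 0L) == 16))
  pm <- catalog_presence("Ash")
  expect_equal(colnames(pm),
               c("At", "Os", "Pa", "Sm", "Pp", "Mp", "Nm", "Kf", "Mr",
                 "Mpu", "Ot", "Ol", "Cv", "Cr", "Vc", "Cp"))
  # "three PHD domains in tandem" in Pp, Mp and Nm only
  expect_equal(colnames(pm)[pm["II-2A", ]], c("Pp", "Mp", "Nm"))
  # PostSET-bearing Ash rows: II-1B in Kf and Cv
  expect_equal(colnames(pm)[pm["II-1B", ]], c("Kf", "Cv"))
  sv <- catalog_presence("Su(var)")
  expect_equal(paste(ifelse(sv["IV-1A", ], "+", "-"), collapse = ""),
               "+++++-++-+--+++-")
})

test_that("catalog loading is idempotent and validates its input", {
  path <- system.file("extdata", "set_catalog.txt", package = "setfam")
  expect_identical(read_catalog(path), read_catalog(path))

  bad <- tempfile(fileext = ".txt")
  writeLines(c("II-9A QQQ-SET extras=- presence=+---------------",
               "II-9B QQQ-SET extras=- presence=-+--------------"), bad)
  expect_error(read_catalog(bad), "duplicate backbone")

  badsp <- tempfile(fileext = ".txt")
  writeLines("species At Os QQ", badsp)
  expect_error(read_catalog(badsp), "unknown species")

  empty <- tempfile(fileext = ".txt")
  writeLines("# nothing here", empty)
  expect_warning(out <- read_catalog(empty), "empty catalog")
  expect_length(out, 0)
})

test_that("domain names canonicalize case-insensitively with passthrough", {
  n <- normalize_domain_name(c("Post-SET", "SET", "zf-c2h2", "FRILLYDOMAIN"))
  expect_equal(as.character(n), c("PostSET", "SET", "ZnF_C2H2",
                                  "FRILLYDOMAIN"))
  expect_equal(attr(n, "extra"), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("hierarchical label ids parse into class/subclass/subdivision", {
  lab <- setfam:::parse_label_id("II-2C")
  expect_equal(lab[c("family", "class_code", "subclass", "subdivision")],
               list(family = "Ash", class_code = "II", subclass = "II-2",
                    subdivision = "II-2C"))
  orp <- setfam:::parse_label_id("IV-Orphan")
  expect_true(orp$family_orphan)
  expect_equal(orp$family, "Su(var)")
  v <- setfam:::parse_label_id("V-SETD")
  expect_equal(v$classv_kind, "SETD")
  expect_error(setfam:::parse_label_id("I-Orphan"), "no Orphan")
})

test_that("species panel is a 16-species permutation in lineage order", {
  sp <- set_species()
  expect_equal(nrow(sp), 16)
  expect_equal(sp$rank, 1:16)
  expect_equal(sp$code[1], "Cp")   # glaucophyta first
  expect_equal(sp$code[16], "At")  # eudicot last
  expect_equal(lineage_order(), sp$code)
})
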