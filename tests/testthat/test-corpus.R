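test_that("XML corpora parse with half-open offsets and canonical labels", {
  path <- example_ddi_xml(tempfile(fileext = ".xml"))
  corp <- read_ddi_xml(path)
  expect_length(corp, 1)
  s <- corp[[1]]$sentences[[1]]
  expect_equal(nrow(s$mentions), 3)
  expect_identical(substr(s$text, s$mentions$start[1] + 1, s$mentions$end[1]),
                   s$mentions$text[1])
  expect_setequal(s$pairs$label, c("Effect", "negative", "Advice"))

  # offsets past the end of the sentence are a parse error naming the id
  bad <- tempfile(fileext = ".xml")
  writeLines(paste0('<corpus><document id="d"><sentence id="s" text="short">',
                    '<entity id="mBAD" charOffset="2-99" type="drug" ',
                    'text="ort"/></sentence></document></corpus>'), bad)
  expect_error(read_ddi_xml(bad), "mBAD")

  # a sentence without entities yields no candidate pairs downstream
  none <- tempfile(fileext = ".xml")
  writeLines(paste0('<corpus><document id="d"><sentence id="s" ',
                    'text="No drugs here."/></document></corpus>'), none)
  expect_equal(nrow(build_instances(read_ddi_xml(none))), 0)

  # discontinuous mentions keep their first contiguous segment
  disc <- tempfile(fileext = ".xml")
  writeLines(paste0('<corpus><document id="d"><sentence id="s" ',
                    'text="alpha and beta blockers">',
                    '<entity id="m1" charOffset="0-4;10-22" type="group" ',
                    'text="alpha blockers"/>',
                    '<entity id="m2" charOffset="10-13" type="drug" ',
                    'text="beta"/>',
                    "</sentence></document></corpus>"), disc)
  got <- read_ddi_xml(disc)[[1]]$sentences[[1]]$mentions
  expect_equal(got$end[1] - got$start[1], 5)
  expect_identical(got$text[1], "alpha")
})

test_that("normalized JSON round-trips the XML corpus", {
  path <- example_ddi_xml(tempfile(fileext = ".xml"))
  corp <- read_ddi_xml(path)
  json <- tempfile(fileext = ".json")
  write_corpus_json(corp, json)
  back <- read_corpus_json(json)
  expect_identical(build_instances(back), build_instances(corp))
})

test_that("pair enumeration gives position-ordered binomial pairs", {
  ex <- example_sentence()
  prs <- enumerate_pairs(ex$mentions)
  expect_equal(nrow(prs), 3)
  expect_true(all(ex$mentions$start[prs$i1] < ex$mentions$start[prs$i2]))
  expect_equal(nrow(enumerate_pairs(ex$mentions[1, , drop = FALSE])), 0)
  five <- data.frame(id = paste0("m", 1:5), start = (0:4) * 10,
                     end = (0:4) * 10 + 3,
                     text = "foo", type = "DRUG")
  expect_equal(nrow(enumerate_pairs(five)), 10)
})

test_that("masking reproduces the three published rows byte-for-byte", {
  ex <- example_sentence()
  m <- ex$mentions
  expect_identical(
    mask_sentence(ex$text, m, 1, 2),
    paste0("Exposure to oral DRUG1 is unaffected by DRUG2 but greatly ",
           "increased by DRUGOTHER."))
  expect_identical(
    mask_sentence(ex$text, m, 1, 3),
    paste0("Exposure to oral DRUG1 is unaffected by DRUGOTHER but greatly ",
           "increased by DRUG2."))
  expect_identical(
    mask_sentence(ex$text, m, 2, 3),
    paste0("Exposure to oral DRUGOTHER is unaffected by DRUG1 but greatly ",
           "increased by DRUG2."))
})

test_that("masking preserves non-mention text and rejects overlaps", {
  text <- "Give ibuprofen, then naproxen."
  drugs <- c("ibuprofen", "naproxen")
  starts <- vapply(drugs, function(x)
    as.integer(regexpr(x, text, fixed = TRUE)) - 1L, 1L)
  m <- data.frame(id = c("a", "b"), start = starts,
                  end = starts + nchar(drugs), text = drugs, type = "DRUG")
  masked <- mask_sentence(text, m, 1, 2)
  expect_identical(masked, "Give DRUG1, then DRUG2.")
  expect_false(grepl("DRUGOTHER", masked))
  # unmasking by reverse substitution recovers the original sentence
  un <- sub("DRUG1", drugs[1], sub("DRUG2", drugs[2], masked), fixed = TRUE)
  expect_identical(un, text)

  overlap <- data.frame(id = c("a", "b"), start = c(5, 7), end = c(14, 12),
                        text = c("ibuprofen", "uprof"), type = "DRUG")
  expect_error(mask_sentence(text, overlap, 1, 2), "overlap")
})

test_that("instances attach gold labels and masked variants coherently", {
  path <- example_ddi_xml(tempfile(fileext = ".xml"))
  inst <- build_instances(read_ddi_xml(path))
  expect_equal(nrow(inst), 3)
  expect_identical(inst$label, c("Effect", "negative", "Advice"))
  # the three masked strings differ only in marker placement
  unmark <- function(x) gsub("DRUG1|DRUG2|DRUGOTHER", "@", x)
  expect_length(unique(unmark(inst$sentence_masked)), 1)
  expect_true(all(vapply(inst$sentence_masked, function(s)
    sum(gregexpr("DRUG1", s, fixed = TRUE)[[1]] > 0) == 1, TRUE)))
})

test_that("linking is normalized-exact with type-dependent spaces", {
  kg <- toy_kg()
  tab <- build_linking_table(kg)
  expect_identical(link_mention(tab, "Aspirin"), "d1")
  expect_identical(link_mention(tab, "  acetylsalicylic   acid "), "d1")
  expect_identical(link_mention(tab, "nonexistent"), NA_character_)
  # GROUP mentions resolve in the category/ATC space only
  expect_identical(link_mention(tab, "anticoagulants", "GROUP"), "c1")
  expect_identical(link_mention(tab, "aspirin", "GROUP"), NA_character_)

  # every synonym surface of a generated graph links back to its entity
  syn <- generate_kg(synthetic_kg_spec(seed = 4, n_drug = 5))
  tab2 <- build_linking_table(syn$kg)
  drugs <- syn$kg$entities[syn$kg$entities$type == "drug", ]
  for (i in seq_len(nrow(drugs))) {
    for (nm in strsplit(drugs$names[i], "|", fixed = TRUE)[[1]]) {
      expect_identical(link_mention(tab2, toupper(nm)), drugs$id[i])
    }
  }

  tsv <- tempfile(fileext = ".tsv")
  write_linking_table(tab, tsv)
  back <- read_linking_table(tsv)
  expect_identical(back$drug, tab$drug)
  expect_identical(back$group, tab$group)
})

test_that("coverage splits into instance-level and unique-mention fractions", {
  inst <- data.frame(
    m1_text = c("a", "a", "b", "c"), m2_text = c("b", "c", "c", "d"),
    kg1 = c("D1", "D1", "D2", "D3"), kg2 = c("D2", "D3", "D3", NA),
    stringsAsFactors = FALSE)
  cov <- coverage(inst)
  expect_equal(cov$instance, 0.75)
  # surfaces a, b, c link; d does not -> 3/4
  expect_equal(cov$mention, 0.75)
  all_in <- inst[1:3, ]
  expect_equal(coverage(all_in)$instance, 1)
  expect_error(coverage(inst[0, ]), "no instances")
})

test_that("instance JSON-lines round-trip", {
  path <- example_ddi_xml(tempfile(fileext = ".xml"))
  kg <- toy_kg()
  inst <- build_instances(read_ddi_xml(path), build_linking_table(kg))
  jl <- tempfile(fileext = ".jsonl")
  write_instances(inst, jl)
  back <- read_instances(jl)
  expect_identical(back$sentence_masked, inst$sentence_masked)
  expect_identical(back$label, inst$label)
  expect_identical(back$kg1, inst$kg1)
})
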