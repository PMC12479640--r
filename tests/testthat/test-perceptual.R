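# Rating schema: presence/consistency rules, the coordination classifier,
# consensus merging and the cohort presence table.

test_that("the parameter inventory is closed", {
  expect_equal(nrow(perceptual_inventory()), 25)
  bad <- make_ratings()
  bad$parameter[1] <- "snoring"
  expect_error(perceptual_profile("n1", "r1", bad),
               class = "swallowCA_unknown_parameter")
  incomplete <- make_ratings()[-3, ]
  expect_error(perceptual_profile("n1", "r1", incomplete),
               class = "swallowCA_bad_table")
})

test_that("presence rule: any occurrence is present; consistency needs > 80% strictly", {
  r <- presence_from_swallows(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))  # 5/6
  expect_equal(r$value, "yes")
  expect_equal(r$consistent, "yes")

  r <- presence_from_swallows(c(TRUE, TRUE, TRUE, TRUE, FALSE))        # 4/5 = 0.80
  expect_equal(r$value, "yes")
  expect_equal(r$consistent, "no")

  r <- presence_from_swallows(rep(FALSE, 7))
  expect_equal(r$value, "no")
  expect_true(is.na(r$consistent))

  expect_error(presence_from_swallows(logical(0)), class = "swallowCA_bad_parameter")
})

test_that("consistency is monotone in added positive swallows", {
  set.seed(61)
  for (i in 1:50) {
    v <- stats::runif(sample(1:12, 1)) < stats::runif(1)
    if (!any(v)) next
    before <- presence_from_swallows(v)$consistent
    after <- presence_from_swallows(c(v, TRUE))$consistent
    if (before == "yes") expect_equal(after, "yes")
  }
})

test_that("coordination classifier follows the clinical rule set", {
  # BTS + normal post-swallow breathing, nothing adventitious: coordinated
  coord <- classify_coordination(make_ratings(
    "during:BTS" = "yes", "post:normal_breathing" = "yes"
  ))
  expect_equal(as.character(coord), "coordinated")

  # BTS without post normal breathing, wet breathing + GRS: uncoordinated
  uncoord <- classify_coordination(make_ratings(
    "during:BTS" = "yes", "during:GRS" = "yes",
    "post:normal_breathing" = "no", "post:wet_breathing" = "yes"
  ))
  expect_equal(as.character(uncoord), "uncoordinated")

  # both rules fire (normal breathing AND stridor post, with GRS):
  # uncoordinated takes precedence
  both <- classify_coordination(make_ratings(
    "during:BTS" = "yes", "during:GRS" = "yes",
    "post:normal_breathing" = "yes", "post:stridor" = "yes"
  ))
  expect_equal(as.character(both), "uncoordinated")

  # identical pre/post breath-sound profiles count as coordinated
  nochange <- classify_coordination(make_ratings(
    "during:BTS" = "yes",
    "pre:normal_breathing" = "yes", "post:normal_breathing" = "yes",
    "pre:stridor" = "yes", "post:stridor" = "yes"
  ))
  expect_equal(as.character(nochange), "coordinated")

  und <- classify_coordination(make_ratings("during:BTS" = "cannot_be_determined"))
  expect_equal(as.character(und), "undetermined")
  expect_match(attr(und, "reason"), "BTS")

  no_bts <- classify_coordination(make_ratings("during:BTS" = "no"))
  expect_equal(as.character(no_bts), "undetermined")
})

test_that("classifier is total over the determined post-swallow hypercube", {
  # BTS = yes, every post-swallow breath sound enumerated yes/no,
  # GRS yes/no, pre profile mirroring post: exactly one of
  # coordinated/uncoordinated, and the precedence rule holds.
  combos <- expand.grid(rep(list(c("yes", "no")), length(BREATH_SOUND_PARAMETERS) + 1),
                        stringsAsFactors = FALSE)
  names(combos) <- c(paste0("post:", BREATH_SOUND_PARAMETERS), "during:GRS")
  advent <- c("wet_breathing", "rattly_chest", "coughing", "wheeze",
              "crackles", "throat_clearing", "stridor")
  for (i in seq_len(nrow(combos))) {
    overrides <- as.list(combos[i, ])
    for (p in BREATH_SOUND_PARAMETERS) {
      overrides[[paste0("pre:", p)]] <- overrides[[paste0("post:", p)]]
    }
    overrides[["during:BTS"]] <- "yes"
    cls <- as.character(classify_coordination(do.call(make_ratings, overrides)))
    expect_true(cls %in% c("coordinated", "uncoordinated"))

    rule1 <- overrides[["post:normal_breathing"]] == "no"
    rule2 <- overrides[["during:GRS"]] == "yes" &&
      any(vapply(advent, function(p) overrides[[paste0("post:", p)]] == "yes", logical(1)))
    expect_equal(cls, if (rule1 || rule2) "uncoordinated" else "coordinated")
  }
})

test_that("consensus passes agreements through and demands resolutions", {
  a <- make_profile("n1", "rater_a", "during:BTS" = "yes", "post:normal_breathing" = "yes")
  b <- make_profile("n1", "rater_b", "during:BTS" = "yes", "post:normal_breathing" = "yes")
  cons <- consensus_profile(a, b)
  expect_equal(cons$rater_id, "consensus")
  expect_equal(cons$ratings, a$ratings)

  b2 <- make_profile("n1", "rater_b", "during:BTS" = "yes", "post:normal_breathing" = "no")
  expect_error(consensus_profile(a, b2), "post:normal_breathing",
               class = "swallowCA_unresolved_disagreement")

  cons2 <- consensus_profile(a, b2, resolutions = list(
    "post:normal_breathing" = list(value = "no")
  ))
  merged <- cons2$ratings
  expect_equal(merged$value[merged$phase == "post" & merged$parameter == "normal_breathing"],
               "no")
  expect_equal(as.character(cons2$coordination), "uncoordinated")

  other <- make_profile("n2", "rater_b", "during:BTS" = "yes")
  expect_error(consensus_profile(a, other), class = "swallowCA_bad_parameter")
})

test_that("cohort presence table uses available-case denominators and half-up rounding", {
  counts <- data.frame(
    phase = c("pre", "post", "post"),
    parameter = c("normal_breathing", "coughing", "stridor"),
    n_present = c(62L, 5L, 33L),
    n_rateable = c(79L, 80L, 80L)
  )
  profiles <- profiles_from_counts(counts, n = 80)
  tab <- cohort_presence_table(profiles, include_coordination = FALSE)
  row <- function(ph, p) tab[tab$phase == ph & tab$parameter == p, ]

  expect_equal(row("pre", "normal_breathing")$n_rateable, 79)
  expect_equal(row("pre", "normal_breathing")$percent, 78.5)
  expect_equal(row("post", "coughing")$percent, 6.3)
  expect_equal(row("post", "stridor")$percent, 41.3)
  expect_equal(row("post", "crackles")$percent, 0.0)

  # ordering invariance
  tab2 <- cohort_presence_table(rev(profiles), include_coordination = FALSE)
  expect_equal(tab2, tab)

  # coordination rows come from the classifier
  tab3 <- cohort_presence_table(profiles)
  expect_true(all(c("coordinated", "uncoordinated") %in% tab3$parameter))
})

test_that("ratings tables round-trip through CSV and profile construction", {
  profs <- list(
    make_profile("n1", "consensus", "during:BTS" = "yes", "post:normal_breathing" = "yes"),
    make_profile("n2", "consensus", "during:BTS" = "yes", "post:wet_breathing" = "yes",
                 "during:GRS" = "yes")
  )
  long <- ratings_from_profiles(profs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(long, path)
  back <- profiles_from_ratings(read_ratings(path))
  expect_length(back, 2)
  expect_equal(back[["n1/consensus"]]$ratings, profs[[1]]$ratings)
  expect_equal(as.character(back[["n2/consensus"]]$coordination), "uncoordinated")
})
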