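test_that("transmission rate counts shared parent CNVRs over parent total", {
  # parent carries A,B,C,D; child carries B,C,E
  cn <- mk_cnvrs(c(0, 1000, 2000, 3000, 4000) * 10,
                 c(500, 10500, 20500, 30500, 40500),
                 carriers = list(c("p"), c("p", "k"), c("p", "k"),
                                 c("p"), c("k")))
  expect_equal(transmission_rate(cn, "p", "k"), 0.5)
  all_shared <- mk_cnvrs(c(0, 1000), c(500, 1600),
                         carriers = list(c("p", "k"), c("p", "k")))
  expect_equal(transmission_rate(all_shared, "p", "k"), 1.0)
  none <- mk_cnvrs(c(0, 1000), c(500, 1600),
                   carriers = list("p", "k"))
  expect_equal(transmission_rate(none, "p", "k"), 0.0)
  # undefined when the parent carries nothing
  expect_true(is.na(transmission_rate(none, "ghostless", "k")))
  expect_error(transmission_rate(none, "zz", "k", samples = c("p", "k")),
               "unknown sample")
})

test_that("inheritance rate checks either parent", {
  # child B,C,E; sire A,B; dam C
  cn <- mk_cnvrs((0:4) * 10000, (0:4) * 10000 + 500,
                 carriers = list("sire", c("sire", "kid"), c("dam", "kid"),
                                 "other", "kid"))
  expect_equal(inheritance_rate(cn, "kid", "sire", "dam"), 2 / 3)
  expect_equal(inheritance_rate(cn, "sire", "kid", "dam"), 0.5)
  solo <- mk_cnvrs(0, 500, carriers = list("kid"))
  expect_equal(inheritance_rate(solo, "kid", "sire", "dam"), 0)
  expect_true(is.na(inheritance_rate(solo, "dam", "kid", "sire")))
})

test_that("trio report aggregates unweighted means and the error rate", {
  cn <- mk_cnvrs((0:3) * 10000, (0:3) * 10000 + 500,
                 carriers = list(c("sire1", "kid1"), c("dam1", "kid1"),
                                 c("sire1"), c("kid2", "sire2", "dam2")))
  trios <- data.frame(child = c("kid1", "kid2"),
                      sire = c("sire1", "sire2"), dam = c("dam1", "dam2"))
  rep <- trio_report(cn, trios)
  expect_equal(nrow(rep$rates), 2)
  expect_equal(rep$rates$inheritance, c(1, 1))
  expect_equal(rep$mean_inheritance, 1)
  expect_equal(rep$error_rate, 0)
  # single trio: means equal that trio's rates
  rep1 <- trio_report(cn, trios[1, ])
  expect_equal(rep1$mean_paternal, rep1$rates$paternal_transmission[1])
  expect_error(trio_report(cn, trios[0, ]), "no trios")
})

test_that("undefined rates are kept as rows but excluded from means", {
  cn <- mk_cnvrs(c(0, 10000), c(500, 10500),
                 carriers = list(c("sire1", "kid1"), c("dam1", "kid1")))
  trios <- data.frame(child = c("kid1", "kid2"),
                      sire = c("sire1", "sire2"), dam = c("dam1", "dam2"))
  expect_warning(rep <- trio_report(cn, trios), "undefined")
  expect_equal(nrow(rep$rates), 2)
  expect_true(is.na(rep$rates$inheritance[2]))
  expect_equal(rep$mean_inheritance, 1)
})

test_that("trios are derived from fully sequenced parent pairs", {
  ped <- data.frame(
    sample = c("s1", "d1", "k1", "k2"),
    sire = c(NA, NA, "s1", "s9"), dam = c(NA, NA, "d1", "d1"),
    sex = c("male", "female", "male", "female"),
    breed = "Duroc", coverage = 10, stringsAsFactors = FALSE)
  tr <- derive_trios(ped)
  expect_equal(tr$child, "k1")   # k2's sire is unsequenced
  expect_equal(tr$sire, "s1")
})
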