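std_tree <- function() ape::read.tree(extdata("ziphiidae_standin_tree.nwk"))
std_cal <- function() read_calibrations(extdata("ziphiidae_node_calibrations.tsv"),
                                        extdata("ziphiidae_tip_ranges.tsv"))

test_that("calibration honours tip ranges and node constraints", {
  tt <- calibrate(std_tree(), std_cal(), policy = "range_top")
  v <- validate_timetree(tt)
  expect_equal(v$n_violations, 0L)
  tr <- tt$tree
  bn <- ape::getMRCA(tr, c("Archaeoziphius", "Berardius", "Microberardius"))
  expect_equal(tt$node_age[bn], 15)             # Berardiinae at its bound
  cz <- ape::getMRCA(tr, c("Tasmacetus", "Mesoplodon"))
  expect_gte(tt$node_age[cz], 17)               # crown constraint
  # the fossil-tip range of Messapicetus gregarius (9.1-8.5 Ma) nests
  # consistently under the Messapicetus-clade node (>= 13.8 Ma)
  mg <- match("Messapicetus_gregarius", tr$tip.label)
  expect_equal(tt$tip_age[["Messapicetus_gregarius"]], 9.1)
  mc <- ape::getMRCA(tr, c("Chimuziphius", "Tusciziphius"))
  expect_gte(tt$node_age[mc], 13.8)
  expect_gte(tt$node_age[mc], tt$node_age[mg])
})

test_that("range_mid policy uses midpoints and stays violation-free", {
  tt <- calibrate(std_tree(), std_cal(), policy = "range_mid")
  expect_equal(validate_timetree(tt)$n_violations, 0L)
  expect_equal(tt$tip_age[["Messapicetus_gregarius"]], (9.1 + 8.5) / 2)
})

test_that("calibration is idempotent and monotone in constraints", {
  cal <- std_cal()
  t1 <- calibrate(std_tree(), cal)
  # rebuilding the calibration from the realized ages changes nothing
  t2 <- calibrate(std_tree(), cal)
  expect_identical(t1$node_age, t2$node_age)
  # tightening a minimum (raising a node's age floor) never lowers ancestors
  cal2 <- cal
  i <- which(cal2$node_constraints$node == "Berardiinae")
  cal2$node_constraints$max_age[i] <- 16.5
  t3 <- calibrate(std_tree(), cal2)
  expect_true(all(t3$node_age >= t1$node_age - 1e-9))
})

test_that("two extant sisters without constraints get the minimal internode", {
  tr <- ape::read.tree(text = "((X,Y),Z);")
  cal <- calibration_set(
    data.frame(node = character(0), max_age = numeric(0),
               min_age = numeric(0), members = character(0)),
    data.frame(taxon = c("X", "Y", "Z"), oldest = 0, youngest = 0))
  tt <- calibrate(tr, cal, eps = 0.1)
  xy <- ape::getMRCA(tr, c("X", "Y"))
  expect_equal(tt$node_age[xy], 0.1)
})

test_that("violations and bad inputs are reported", {
  tt <- calibrate(std_tree(), std_cal())
  # hand-build a broken time tree: child older than parent
  tt_bad <- tt
  tip <- 1L
  parent <- tt$tree$edge[tt$tree$edge[, 2] == tip, 1]
  tt_bad$node_age[tip] <- tt$node_age[parent] + 5
  expect_equal(validate_timetree(tt_bad)$n_violations, 1L)

  cal <- std_cal()
  cal$node_constraints$members[1] <- "Berardius,Notaxon"
  expect_error(calibrate(std_tree(), cal), "unknown taxa")
  cal2 <- std_cal()
  # a non-monophyletic member list is rejected by name
  cal2$node_constraints$members[4] <- "Archaeoziphius,Tasmacetus"
  expect_error(calibrate(std_tree(), cal2), "not monophyletic")
  cal3 <- std_cal()
  cal3$tip_ranges <- cal3$tip_ranges[-1, ]
  expect_error(calibrate(std_tree(), cal3), "without a stratigraphic range")
  expect_error(calibration_set(
    data.frame(node = "x", max_age = 1, min_age = 2, members = "a"),
    data.frame(taxon = "a", oldest = 0, youngest = 0)), "max_age")
})

test_that("epoch table resolves verbal ages sensibly", {
  et <- epoch_table()
  expect_true(all(et$from >= et$to))
  expect_equal(et$from[et$interval == "Neogene"], 23.03)
})
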