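# Independent brute-force evaluation of the exposure equation, written as
# literal lookups so it shares no code with the package implementation.
# Covers brickless reports for the 11 canonical segments.

oracle_route_mfs <- function(segment, age) {
  if (segment == "Kitchen Merchandise") {
    return(c(oral = 3, dermal = 2, inhalation = 1))
  }
  # every other brickless segment is dermal-primary; under-3 adds oral
  # secondary; inhalation (and oral for 3+) floors at tertiary
  c(oral = if (age == "under_three") 2 else 1, dermal = 3, inhalation = 1)
}

oracle_exposure <- function(segment, age, bin, chem) {
  ls <- if (age == "under_three") 3 else 1
  ex <- if (segment %in% c("Clothing", "Footwear",
                           "Beauty/Personal Care/Hygiene", "Camping")) 3 else 1
  a <- if (segment == "Beauty/Personal Care/Hygiene") 3 else 1
  con <- c("lt100" = 0.5, "100-500" = 1, "500-1000" = 1.5,
           "1000-5000" = 2, "5000-10000" = 2.5, "gt10000" = 3)[[bin]]
  mf <- oracle_route_mfs(segment, age)
  tk <- function(prop, abs) {
    if (is.na(prop)) return(abs)
    if (is.na(abs)) return(prop)
    (prop + abs) / 2
  }
  ls + ex + a + con +
    mf[["oral"]] * tk(chem$solubility_score, chem$abs_oral_score) +
    mf[["dermal"]] * tk(chem$kp_score, chem$abs_dermal_score) +
    mf[["inhalation"]] * tk(chem$vp_score, chem$abs_inhalation_score)
}

make_report <- function(chemical_id = "styrene", segment = "Clothing",
                        target_age = "three_to_twelve",
                        concentration_bin = "lt100", brick = NA,
                        report_id = "t1") {
  res <- validate_report(list(
    report_id = report_id, chemical_id = chemical_id, segment = segment,
    brick = brick, target_age = target_age,
    concentration_bin = concentration_bin
  ))
  stopifnot(res$valid)
  res$report
}
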