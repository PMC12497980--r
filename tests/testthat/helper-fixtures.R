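# Hand-built FAERS-dialect fixtures assembled in code.

demo_row <- function(primaryid, caseid = primaryid, fda_dt = "20230101",
                     event_dt = "", sex = "M", age = "60",
                     age_cod = "YR", wt = "", wt_cod = "",
                     occp_cod = "MD", reporter_country = "US") {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = event_dt, sex = sex, age = age,
             age_cod = age_cod, wt = wt, wt_cod = wt_cod,
             occp_cod = occp_cod, reporter_country = reporter_country,
             stringsAsFactors = FALSE)
}

drug_row <- function(primaryid, drugname, role_cod = "PS",
                     drug_seq = "1", prod_ai = "") {
  data.frame(primaryid = primaryid, drug_seq = drug_seq,
             role_cod = role_cod, drugname = drugname,
             prod_ai = prod_ai, stringsAsFactors = FALSE)
}

reac_row <- function(primaryid, pt) {
  data.frame(primaryid = primaryid, pt = pt, stringsAsFactors = FALSE)
}

ther_row <- function(primaryid, start_dt, dsg_drug_seq = "1",
                     end_dt = "") {
  data.frame(primaryid = primaryid, dsg_drug_seq = dsg_drug_seq,
             start_dt = start_dt, end_dt = end_dt,
             stringsAsFactors = FALSE)
}

outc_row <- function(primaryid, outc_cod = "OT") {
  data.frame(primaryid = primaryid, outc_cod = outc_cod,
             stringsAsFactors = FALSE)
}

empty_ther <- function() {
  data.frame(primaryid = character(0), dsg_drug_seq = character(0),
             start_dt = character(0), end_dt = character(0),
             stringsAsFactors = FALSE)
}
empty_outc <- function() {
  data.frame(primaryid = character(0), outc_cod = character(0),
             stringsAsFactors = FALSE)
}

make_faers <- function(demo, drug, reac, ther = empty_ther(),
                       outc = empty_outc()) {
  faers_data(list(demo = demo, drug = drug, reac = reac, ther = ther,
                  outc = outc))
}

# a small mixed dataset: 8 reports, 2 ICI-PS event cases, one role-C
# ICI report, one multi-ICI report, background reports
small_faers <- function() {
  demo <- rbind(
    demo_row("1", sex = "M", age = "70", event_dt = "20230110"),
    demo_row("2", sex = "F", age = "50", event_dt = "20230210"),
    demo_row("3", sex = "M", age = "40"),
    demo_row("4", sex = "F", age = "80"),
    demo_row("5", sex = "", age = ""),
    demo_row("6", sex = "M", age = "55"),
    demo_row("7", sex = "F", age = "62"),
    demo_row("8", sex = "M", age = "71")
  )
  drug <- rbind(
    drug_row("1", "OPDIVO"),                       # ICI PS, event
    drug_row("2", "KEYTRUDA 200MG"),               # ICI PS, event
    drug_row("3", "NIVOLUMAB", role_cod = "C"),    # ICI but concomitant
    drug_row("4", "ASPIRIN"),
    drug_row("5", "METFORMIN"),
    drug_row("6", "YERVOY"),                       # ICI PS, no event
    drug_row("7", "OPDIVO"),                       # multi-ICI PS report
    drug_row("7", "YERVOY", drug_seq = "2"),
    drug_row("8", "ATORVASTATIN")
  )
  reac <- rbind(
    reac_row("1", "Pancreatitis"),
    reac_row("2", "Immune-mediated pancreatitis"),
    reac_row("3", "Pancreatitis"),
    reac_row("4", "Pancreatitis"),
    reac_row("5", "Nausea"),
    reac_row("6", "Rash"),
    reac_row("7", "Pancreatitis acute"),
    reac_row("8", "Fatigue")
  )
  ther <- rbind(
    ther_row("1", "20230101"),
    ther_row("2", "202301"),
    ther_row("7", "20221201"),
    ther_row("7", "20221215", dsg_drug_seq = "2")
  )
  outc <- rbind(
    outc_row("1", "DE"),
    outc_row("2", "HO"),
    outc_row("7", "OT")
  )
  make_faers(demo, drug, reac, ther, outc)
}
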