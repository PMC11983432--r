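# Published VigiAccess summary counts for the three androgen-receptor
# antagonists (apalutamide, darolutamide, enzalutamide), transcribed as
# ready-made fixtures. Record-level VigiAccess data is not publicly
# downloadable, so these printed numerators/denominators are the only
# real-data inputs available for regression-testing the percentage and
# comparison logic.

.drugs3 <- c("apalutamide", "darolutamide", "enzalutamide")

#' Published report totals per drug
#' @return Tibble `drug`, `n_reports` (11,452 / 2,269 / 53,007).
#' @export
vigiaccess_report_counts <- function() {
  tibble::tibble(drug = .drugs3, n_reports = c(11452L, 2269L, 53007L))
}

#' Published reaction (PT occurrence) totals per drug
#' @return Tibble `drug`, `n_reactions` (20,965 / 5,236 / 145,819).
#' @export
vigiaccess_reaction_totals <- function() {
  tibble::tibble(drug = .drugs3, n_reactions = c(20965L, 5236L, 145819L))
}

#' Published demographic distributions of ADR reports
#'
#' Report-level counts and printed percentages per drug along the four
#' demographic axes (sex, age band, continent, reporting year). The
#' denominator of each percentage is the drug's report total.
#'
#' @return Tibble `drug`, `axis`, `stratum`, `count`, `percent` (the
#'   printed two-decimal value).
#' @export
vigiaccess_demographics <- function() {
  row <- function(axis, stratum, counts, pcts) {
    tibble::tibble(
      drug = .drugs3, axis = axis, stratum = stratum,
      count = as.integer(counts), percent = pcts
    )
  }
  dplyr::bind_rows(
    row("sex", "Female", c(35, 7, 313), c(0.31, 0.31, 0.59)),
    row("sex", "Male", c(10751, 2124, 51764), c(93.88, 93.61, 97.66)),
    row("sex", "Unknown", c(666, 138, 930), c(5.82, 6.08, 1.75)),
    row("age_group", "<18", c(3, 2, 7), c(0.03, 0.09, 0.01)),
    row("age_group", "18-44", c(10, 3, 58), c(0.09, 0.13, 0.11)),
    row("age_group", "45-64", c(722, 262, 4091), c(6.30, 11.55, 7.72)),
    row("age_group", "65-74", c(2217, 495, 9422), c(19.36, 21.82, 17.78)),
    row("age_group", ">=75", c(3624, 777, 17308), c(31.65, 34.24, 32.65)),
    row("age_group", "Unknown", c(4876, 730, 22121), c(42.58, 32.17, 41.73)),
    row("continent", "Africa", c(141, 0, 65), c(1.23, 0.00, 0.12)),
    row("continent", "Americas", c(5932, 1127, 42759), c(51.80, 49.67, 80.67)),
    row("continent", "Asia", c(1639, 368, 4220), c(14.31, 16.22, 7.96)),
    row("continent", "Europe", c(3724, 718, 5648), c(32.52, 31.64, 10.66)),
    row("continent", "Oceania", c(16, 56, 315), c(0.14, 2.47, 0.59)),
    row("year", "Before 2017", c(3, 2, 14551), c(0.03, 0.09, 27.45)),
    row("year", "2017", c(4, 2, 8209), c(0.03, 0.09, 15.49)),
    row("year", "2018", c(75, 0, 10471), c(0.65, 0.00, 19.75)),
    row("year", "2019", c(844, 11, 7789), c(7.37, 0.48, 14.69)),
    row("year", "2020", c(1091, 97, 2094), c(9.53, 4.28, 3.95)),
    row("year", "2021", c(1317, 242, 2238), c(11.50, 10.67, 4.22)),
    row("year", "2022", c(2191, 336, 2140), c(19.13, 14.81, 4.04)),
    row("year", "2023", c(2385, 580, 2361), c(20.83, 25.56, 4.45)),
    row("year", "2024", c(3542, 999, 3154), c(30.93, 44.03, 5.95))
  )
}

# the 26 analyzed SOCs, in published row order
.soc26 <- c(
  "Blood and lymphatic system disorders",
  "Cardiac disorders",
  "Congenital, familial and genetic disorders",
  "Ear and labyrinth disorders",
  "Endocrine disorders",
  "Eye disorders",
  "Gastrointestinal disorders",
  "General disorders and administration site conditions",
  "Hepatobiliary disorders",
  "Immune system disorders",
  "Infections and infestations",
  "Injury, poisoning and procedural complications",
  "Investigations",
  "Metabolism and nutrition disorders",
  "Musculoskeletal and connective tissue disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "Nervous system disorders",
  "Psychiatric disorders",
  "Renal and urinary disorders",
  "Reproductive system and breast disorders",
  "Respiratory, thoracic and mediastinal disorders",
  "Skin and subcutaneous tissue disorders",
  "Social circumstances",
  "Surgical and medical procedures",
  "Vascular disorders",
  "Product issues"
)

#' The 26 analyzed system organ classes
#' @return Character vector in published row order.
#' @export
vigiaccess_soc_list <- function() .soc26

#' Published SOC-level reaction counts and rates
#'
#' Reaction-level counts per SOC and the printed percentages; the
#' denominator is each drug's reaction total (see
#' [vigiaccess_reaction_totals()]), not its report count. The excluded
#' pregnancy/puerperium SOC is not part of the 26 rows, which is why the
#' enzalutamide column sums to slightly less than its printed N.
#'
#' @return Tibble `drug`, `soc`, `count`, `percent`.
#' @export
vigiaccess_soc_rates <- function() {
  apal <- c(280, 486, 7, 90, 195, 133, 1328, 3835, 103, 83, 586, 1443, 1482,
            447, 973, 604, 1495, 514, 326, 132, 574, 4078, 40, 594, 1056, 81)
  apal_pct <- c(1.34, 2.32, 0.03, 0.43, 0.93, 0.63, 6.33, 18.29, 0.49, 0.40,
                2.80, 6.88, 7.07, 2.13, 4.64, 2.88, 7.13, 2.45, 1.56, 0.63,
                2.74, 19.45, 0.19, 2.83, 5.04, 0.39)
  daro <- c(113, 119, 1, 22, 5, 55, 469, 992, 85, 19, 142, 366, 512, 111,
            370, 246, 433, 147, 127, 57, 172, 369, 17, 83, 199, 5)
  daro_pct <- c(2.16, 2.27, 0.02, 0.42, 0.10, 1.05, 8.96, 18.95, 1.62, 0.36,
                2.71, 6.99, 9.78, 2.12, 7.07, 4.70, 8.27, 2.81, 2.43, 1.09,
                3.29, 7.05, 0.33, 1.59, 3.80, 0.10)
  enza <- c(1205, 2241, 30, 715, 98, 1661, 14604, 35797, 461, 328, 4007,
            10731, 10219, 4709, 10467, 7216, 15569, 5887, 2645, 785, 4407,
            4196, 356, 1208, 4884, 1391)
  enza_pct <- c(0.83, 1.54, 0.02, 0.49, 0.07, 1.14, 10.02, 24.55, 0.32, 0.23,
                2.75, 7.36, 7.01, 3.23, 7.18, 4.95, 10.68, 4.04, 1.81, 0.54,
                3.02, 2.88, 0.24, 0.83, 3.35, 0.95)
  dplyr::bind_rows(
    tibble::tibble(drug = "apalutamide", soc = .soc26, count = as.integer(apal), percent = apal_pct),
    tibble::tibble(drug = "darolutamide", soc = .soc26, count = as.integer(daro), percent = daro_pct),
    tibble::tibble(drug = "enzalutamide", soc = .soc26, count = as.integer(enza), percent = enza_pct)
  )
}

#' Published top-20 PT report rates
#'
#' The twenty most frequent preferred terms per drug with their printed
#' report rates (percent of each drug's reaction total).
#'
#' @return Tibble `drug`, `rank`, `pt`, `rate`.
#' @export
vigiaccess_top_pt <- function() {
  apal <- c(
    "Rash" = 9.93, "Fatigue" = 4.25, "Death" = 4.17, "Hot flush" = 2.59,
    "Product dose omission issue" = 1.77, "Diarrhoea" = 1.72,
    "Pruritus" = 1.47, "Hypertension" = 1.46, "Arthralgia" = 1.45,
    "Asthenia" = 1.42, "Prostatic specific antigen increased" = 1.33,
    "Dizziness" = 1.23, "Off label use" = 1.18, "Fall" = 1.17,
    "Drug ineffective" = 1.06, "Decreased appetite" = 1.01, "Nausea" = 0.94,
    "Rash pruritic" = 0.88, "Weight decreased" = 0.83,
    "Interstitial lung disease" = 0.77
  )
  daro <- c(
    "Fatigue" = 6.26, "Rash" = 2.46, "Off label use" = 2.39, "Death" = 2.23,
    "Asthenia" = 2.18, "Diarrhoea" = 1.83, "Hot flush" = 1.83,
    "Prostatic specific antigen increased" = 1.53, "Pain in extremity" = 1.45,
    "Nausea" = 1.43, "Dizziness" = 1.28, "Arthralgia" = 1.20,
    "Dyspnoea" = 1.15, "Decreased appetite" = 1.07,
    "Neuropathy peripheral" = 1.03, "Product dose omission issue" = 0.94,
    "Hormone-refractory prostate cancer" = 0.94, "Hypertension" = 0.90,
    "Prostate cancer" = 0.84, "Peripheral swelling" = 0.78
  )
  enza <- c(
    "Fatigue" = 6.34, "Death" = 4.75, "Malignant neoplasm progression" = 3.37,
    "Drug ineffective" = 2.63, "Prostatic specific antigen increased" = 2.53,
    "Asthenia" = 2.48, "Decreased appetite" = 2.09, "Nausea" = 2.06,
    "Hot flush" = 1.98, "Dizziness" = 1.86, "Diarrhoea" = 1.72,
    "Back pain" = 1.35, "Underdose" = 1.34, "Arthralgia" = 1.22,
    "Constipation" = 1.05, "Headache" = 1.04, "Weight decreased" = 1.03,
    "Fall" = 1.02, "Pain" = 0.94, "Malaise" = 0.87
  )
  one <- function(drug, v) {
    tibble::tibble(drug = drug, rank = seq_along(v), pt = names(v), rate = unname(v))
  }
  dplyr::bind_rows(
    one("apalutamide", apal), one("darolutamide", daro), one("enzalutamide", enza)
  )
}

#' Published serious-AE summary
#'
#' Reaction totals paired with the published serious-outcome rates
#' (death, hospitalization, disability combined). The underlying outcome
#' counts were published only graphically and are not transcribed.
#'
#' @return Tibble `drug`, `n_reactions`, `percent`.
#' @export
vigiaccess_serious_rates <- function() {
  tibble::tibble(
    drug = .drugs3,
    n_reactions = c(20965L, 5236L, 145819L),
    percent = c(4.94, 2.85, 5.06)
  )
}

#' Published PT signals shared by all three drugs
#'
#' The shared-signal table: per SOC, the PTs signalled for all three
#' drugs and the published per-SOC signal count. Transcribed as printed:
#' note that the "General disorders and administration site conditions"
#' row lists 26 PTs against a printed Signal N of 25 (the published
#' counts column sums to 162, the listed PTs to 163).
#'
#' @return Tibble `soc`, `pts` (list-column), `signal_n` (printed count).
#' @export
vigiaccess_shared_adrs <- function() {
  rows <- list(
    list(
      "General disorders and administration site conditions",
      c("Peripheral swelling", "Gait inability", "Pyrexia", "Disease progression",
        "Oedema", "Chest discomfort", "Swelling face", "Chest pain", "Asthenia",
        "Adverse drug reaction", "Drug ineffective", "Drug intolerance",
        "Gait disturbance", "Death", "General physical health deterioration",
        "Oedema peripheral", "Pain", "Drug interaction", "Condition aggravated",
        "Chills", "Malaise", "Fatigue", "Illness", "Feeling hot",
        "Feeling abnormal", "Adverse event"),
      25L
    ),
    list(
      "Nervous system disorders",
      c("Taste disorder", "Transient ischaemic attack", "Dysgeusia", "Somnolence",
        "Loss of consciousness", "Hypersomnia", "Paraesthesia", "Memory impairment",
        "Ageusia", "Dementia", "Hypoaesthesia", "Headache", "Syncope",
        "Neuropathy peripheral", "Tremor", "Cognitive disorder", "Balance disorder",
        "Cerebrovascular accident", "Seizure", "Dizziness", "Lethargy"),
      21L
    ),
    list(
      "Gastrointestinal disorders",
      c("Abdominal distension", "Vomiting", "Diarrhoea", "Abdominal discomfort",
        "Dyspepsia", "Abdominal pain upper", "Dry mouth",
        "Gastrooesophageal reflux disease", "Gastrointestinal disorder", "Nausea",
        "Abdominal pain", "Flatulence", "Dysphagia", "Constipation"),
      14L
    ),
    list(
      "Musculoskeletal and connective tissue disorders",
      c("Joint swelling", "Arthralgia", "Bone pain", "Limb discomfort", "Back pain",
        "Mobility decreased", "Muscle atrophy", "Pain in extremity", "Myalgia",
        "Musculoskeletal pain", "Muscle spasms", "Muscular weakness", "Arthritis"),
      13L
    ),
    list(
      "Skin and subcutaneous tissue disorders",
      c("Erythema", "Urticaria", "Alopecia", "Dry skin", "Night sweats",
        "Rash pruritic", "Pruritus", "Skin exfoliation", "Rash", "Hyperhidrosis"),
      10L
    ),
    list(
      "Injury, poisoning and procedural complications",
      c("Product use in unapproved indication", "Fracture", "Off label use",
        "Hip fracture", "Incorrect dose administered", "Fall",
        "Wrong technique in product usage process",
        "Inappropriate schedule of product administration",
        "Product dose omission issue"),
      9L
    ),
    list(
      "Investigations",
      c("Weight decreased", "Prostatic specific antigen increased",
        "Blood glucose increased", "Blood pressure decreased",
        "Blood pressure increased", "Heart rate increased", "Weight increased",
        "White blood cell count decreased", "Haemoglobin decreased"),
      9L
    ),
    list(
      "Infections and infestations",
      c("Nasopharyngitis", "Urinary tract infection", "Pneumonia", "Herpes zoster",
        "Influenza", "Infection", "Sepsis", "COVID-19"),
      8L
    ),
    list(
      "Renal and urinary disorders",
      c("Renal impairment", "Acute kidney injury", "Dysuria", "Haematuria",
        "Pollakiuria", "Urinary retention", "Nocturia", "Renal failure"),
      8L
    ),
    list(
      "Psychiatric disorders",
      c("Insomnia", "Hallucination", "Anxiety", "Depression", "Eating disorder",
        "Confusional state", "Sleep disorder"),
      7L
    ),
    list(
      "Respiratory, thoracic and mediastinal disorders",
      c("Oropharyngeal pain", "Dyspnoea", "Pulmonary embolism",
        "Interstitial lung disease", "Epistaxis", "Dyspnoea exertional", "Cough"),
      7L
    ),
    list(
      "Cardiac disorders",
      c("Cardiac failure", "Cardiac failure congestive", "Cardiac disorder",
        "Cardiac arrest", "Myocardial infarction", "Atrial fibrillation"),
      6L
    ),
    list(
      "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
      c("Metastases to bone", "Hormone-refractory prostate cancer",
        "Prostate cancer", "Prostate cancer metastatic",
        "Malignant neoplasm progression", "Neoplasm malignant"),
      6L
    ),
    list(
      "Vascular disorders",
      c("Hot flush", "Blood pressure fluctuation", "Hypertension", "Thrombosis",
        "Hypotension"),
      5L
    ),
    list(
      "Blood and lymphatic system disorders",
      c("Neutropenia", "Anaemia", "Thrombocytopenia"),
      3L
    ),
    list("Ear and labyrinth disorders", c("Tinnitus", "Vertigo"), 2L),
    list("Eye disorders", c("Visual impairment", "Vision blurred"), 2L),
    list("Metabolism and nutrition disorders", c("Dehydration", "Decreased appetite"), 2L),
    list(
      "Reproductive system and breast disorders",
      c("Gynaecomastia", "Erectile dysfunction"), 2L
    ),
    list("Hepatobiliary disorders", "Hepatic function abnormal", 1L),
    list("Immune system disorders", "Hypersensitivity", 1L),
    list("Surgical and medical procedures", "Hospitalisation", 1L)
  )
  tibble::tibble(
    soc = vapply(rows, `[[`, character(1), 1),
    pts = lapply(rows, `[[`, 2),
    signal_n = vapply(rows, `[[`, integer(1), 3)
  )
}

#' Published drug-exclusive PT signals
#'
#' The distinct-signal table: PTs signalled for exactly one of the three
#' drugs, by SOC. Blank cells of the published layout are simply absent
#' rows here.
#'
#' @return Tibble `soc`, `drug`, `pts` (list-column).
#' @export
vigiaccess_distinct_adrs <- function() {
  rows <- list(
    list("Blood and lymphatic system disorders", "apalutamide",
         c("Eosinophilia", "Agranulocytosis")),
    list("Blood and lymphatic system disorders", "darolutamide",
         c("Myelosuppression", "Disseminated intravascular coagulation",
           "Cytopenia", "Blood disorder")),
    list("Cardiac disorders", "apalutamide",
         c("Myocardial ischaemia", "Acute myocardial infarction")),
    list("Cardiac disorders", "darolutamide", c("Cardiotoxicity", "Bradycardia")),
    list("Endocrine disorders", "apalutamide",
         c("Hypothyroidism", "Thyroid disorder")),
    list("Eye disorders", "darolutamide", "Blindness"),
    list("Eye disorders", "enzalutamide", "Cataract"),
    list("Gastrointestinal disorders", "apalutamide", "Rectal haemorrhage"),
    list("Gastrointestinal disorders", "darolutamide",
         c("Faeces soft", "Frequent bowel movements", "Colitis",
           "Faeces discoloured", "Gastrointestinal motility disorder",
           "Swollen tongue")),
    list("Gastrointestinal disorders", "enzalutamide",
         c("Retching", "Gastrointestinal haemorrhage")),
    list("General disorders and administration site conditions", "apalutamide",
         "Therapeutic product effect decreased"),
    list("General disorders and administration site conditions", "darolutamide",
         c("Pre-existing condition improved", "Feeling cold",
           "Exercise tolerance decreased")),
    list("General disorders and administration site conditions", "enzalutamide",
         c("Treatment failure", "Influenza like illness")),
    list("Hepatobiliary disorders", "darolutamide",
         c("Hepatic cytolysis", "Hypertransaminasaemia", "Hepatitis")),
    list("Infections and infestations", "apalutamide",
         "Lower respiratory tract infection"),
    list("Infections and infestations", "darolutamide", "Escherichia infection"),
    list("Injury, poisoning and procedural complications", "apalutamide",
         c("Incorrect dosage administered", "Intentional product use issue")),
    list("Injury, poisoning and procedural complications", "darolutamide",
         c("Limb injury", "Toxicity to various agents",
           "Incorrect product administration duration", "Multiple fractures",
           "Product prescribing issue", "Product dose omission in error",
           "Accidental exposure to product", "Nerve injury")),
    list("Injury, poisoning and procedural complications", "enzalutamide",
         c("Product storage error", "Intentional product misuse", "Overdose",
           "Underdose",
           "Circumstance or information capable of leading to medication error",
           "Intentional dose omission", "Foreign body in throat")),
    list("Investigations", "apalutamide",
         c("Glycosylated haemoglobin increased", "Blood potassium increased",
           "Blood triglycerides increased",
           "Blood thyroid stimulating hormone increased",
           "Laboratory test abnormal", "Prostatic specific antigen decreased")),
    list("Investigations", "darolutamide",
         c("Blood sodium decreased", "Blood calcium decreased",
           "Red blood cell count decreased", "Transaminases increased",
           "Blood bilirubin increased", "Heart rate decreased",
           "International normalised ratio increased",
           "Blood potassium decreased", "Blood testosterone decreased")),
    list("Investigations", "enzalutamide", "Full blood count decreased"),
    list("Metabolism and nutrition disorders", "apalutamide",
         c("Hyperkalaemia", "Hypercholesterolaemia")),
    list("Metabolism and nutrition disorders", "darolutamide", "Increased appetite"),
    list("Metabolism and nutrition disorders", "enzalutamide", "Hypophagia"),
    list("Musculoskeletal and connective tissue disorders", "apalutamide",
         "Osteoporosis"),
    list("Musculoskeletal and connective tissue disorders", "darolutamide",
         c("Rhabdomyolysis", "Musculoskeletal discomfort",
           "Musculoskeletal disorder", "Groin pain")),
    list("Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
         "apalutamide", "Lung neoplasm malignant"),
    list("Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
         "darolutamide",
         c("Bladder cancer", "Neoplasm progression", "Metastases to spine",
           "Metastases to pelvis", "Malignant melanoma")),
    list("Nervous system disorders", "apalutamide",
         c("Sensory disturbance", "Cerebral infarction")),
    list("Nervous system disorders", "darolutamide",
         c("Head discomfort", "Parkinson's disease", "Motor dysfunction",
           "Neuralgia", "Presyncope")),
    list("Nervous system disorders", "enzalutamide", "Dyskinesia"),
    list("Product issues", "apalutamide",
         c("Product label issue", "Product packaging quantity issue")),
    list("Product issues", "enzalutamide",
         c("Product availability issue", "Product physical issue")),
    list("Psychiatric disorders", "darolutamide",
         c("Poor quality sleep", "Delirium", "Apathy", "Stress",
           "Personality change")),
    list("Psychiatric disorders", "enzalutamide",
         c("Disorientation", "Restlessness")),
    list("Renal and urinary disorders", "apalutamide", "Micturition urgency"),
    list("Renal and urinary disorders", "darolutamide", "Urinary tract disorder"),
    list("Reproductive system and breast disorders", "apalutamide",
         c("Pelvic pain", "Breast enlargement")),
    list("Reproductive system and breast disorders", "darolutamide",
         c("Breast swelling", "Breast pain")),
    list("Respiratory, thoracic and mediastinal disorders", "darolutamide",
         c("Pulmonary hypertension", "Lung disorder", "Pneumonitis")),
    list("Respiratory, thoracic and mediastinal disorders", "enzalutamide",
         c("Choking", "Pleural effusion", "Throat irritation",
           "Chronic obstructive pulmonary disease", "Rhinorrhoea",
           "Productive cough")),
    list("Skin and subcutaneous tissue disorders", "apalutamide",
         c("Lichenoid keratosis", "Skin toxicity",
           "Drug reaction with eosinophilia and systemic symptoms",
           "Erythema multiforme", "Toxic epidermal necrolysis", "Eczema",
           "Dermatitis allergic", "Stevens-johnson syndrome",
           "Toxic skin eruption", "Dermatitis", "Skin reaction",
           "Dermatitis exfoliative generalised")),
    list("Skin and subcutaneous tissue disorders", "darolutamide",
         c("Haemorrhage subcutaneous", "Skin atrophy",
           "Palmar-plantar erythrodysaesthesia syndrome", "Angioedema",
           "Nail disorder")),
    list("Social circumstances", "darolutamide", "Bedridden"),
    list("Surgical and medical procedures", "apalutamide",
         c("Therapy change", "Surgery")),
    list("Surgical and medical procedures", "darolutamide", "Cardiac operation"),
    list("Vascular disorders", "darolutamide",
         c("Deep vein thrombosis", "Orthostatic hypotension"))
  )
  tibble::tibble(
    soc = vapply(rows, `[[`, character(1), 1),
    drug = vapply(rows, `[[`, character(1), 2),
    pts = lapply(rows, `[[`, 3)
  )
}

#' Bundled PT to SOC map
#'
#' A toy MedDRA-like dictionary built from the union of the shared and
#' drug-exclusive signal tables (about 270 PTs), with the SOC list of the
#' 26 analyzed system organ classes. It stands in for a licensed MedDRA
#' hierarchy in examples, simulations and tests.
#'
#' @return A [meddra_map()].
#' @export
meddra_fixture_map <- function() {
  shared <- vigiaccess_shared_adrs()
  distinct <- vigiaccess_distinct_adrs()
  pt <- c(
    unlist(shared$pts, use.names = FALSE),
    unlist(distinct$pts, use.names = FALSE)
  )
  soc <- c(
    rep.int(shared$soc, lengths(shared$pts)),
    rep.int(distinct$soc, lengths(distinct$pts))
  )
  meddra_map(pt, soc, soc_levels = .soc26)
}

#' All published-count fixtures in one list
#'
#' Convenience bundle of the transcribed summary tables used as
#' regression inputs for the percentage and comparison logic.
#'
#' @return Named list: `report_counts`, `reaction_totals`,
#'   `demographics`, `soc_rates`, `top_pt`, `serious_rates`,
#'   `shared_adrs`, `distinct_adrs`, `map`.
#' @export
fixture_paper_counts <- function() {
  list(
    report_counts = vigiaccess_report_counts(),
    reaction_totals = vigiaccess_reaction_totals(),
    demographics = vigiaccess_demographics(),
    soc_rates = vigiaccess_soc_rates(),
    top_pt = vigiaccess_top_pt(),
    serious_rates = vigiaccess_serious_rates(),
    shared_adrs = vigiaccess_shared_adrs(),
    distinct_adrs = vigiaccess_distinct_adrs(),
    map = meddra_fixture_map()
  )
}

#' Transcribed per-drug signal sets
#'
#' Reconstructs the three drugs' PT-level signal sets implied by the
#' published comparison: each drug's set is the union of the shared PTs
#' and its own exclusive PTs (partially shared PTs were not published).
#'
#' @return A list of three [signal_set()] objects.
#' @export
vigiaccess_signal_sets <- function() {
  shared <- vigiaccess_shared_adrs()
  shared_events <- tibble::tibble(
    pt = unlist(shared$pts, use.names = FALSE),
    soc = rep.int(shared$soc, lengths(shared$pts))
  )
  distinct <- vigiaccess_distinct_adrs()
  lapply(stats::setNames(.drugs3, .drugs3), function(d) {
    rows <- distinct[distinct$drug == d, ]
    own <- tibble::tibble(
      pt = unlist(rows$pts, use.names = FALSE),
      soc = rep.int(rows$soc, lengths(rows$pts))
    )
    signal_set(d, dplyr::bind_rows(shared_events, own))
  })
}
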