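# ---------------------------------------------------------------------------
# Synthetic vignette generator with planted ground truth. Narratives are
# rendered from templates in the same canonical formats the extractor parses,
# and all threshold-adjacent values keep a guard margin away from rule
# boundaries (boundary-stress mode samples exactly at thresholds instead).
# ---------------------------------------------------------------------------

.categories <- c(calculous = 6L, acalculous = 2L, complicated = 5L,
                 chronic_biliary = 4L, polyps = 3L, mirizzi = 2L,
                 carcinoma = 4L, postchole = 4L)
.domains <- c(diagnosis = 10L, treatment = 10L, complications = 10L)

#' Generation specification for a synthetic question bank
#'
#' Defaults reproduce the study instrument's structure: 30 items stratified
#' 10/10/10 over clinical domains and 6/2/5/4/3/2/4/4 over the eight disease
#' categories.
#'
#' @param categories named integer vector of per-category item counts.
#' @param domains named integer vector of per-domain item counts.
#' @param grade_dist probabilities for planted grades I/II/III on acute
#'   items.
#' @param noise_rate expected number of irrelevant-finding sentences per
#'   vignette.
#' @param guard_frac guard margin, as a fraction of each threshold, kept
#'   between sampled values and rule boundaries.
#' @param seed mandatory integer seed.
#' @return a list of class `tg18_genspec`.
#' @export
generation_spec <- function(categories = .categories, domains = .domains,
                            grade_dist = c(I = 0.4, II = 0.35, III = 0.25),
                            noise_rate = 0, guard_frac = 0.05, seed) {
  if (missing(seed)) abort_tg18("seed is mandatory", "tg18_validation_error")
  if (sum(categories) != sum(domains)) {
    abort_tg18("category counts and domain counts must sum to the same bank size",
               "tg18_validation_error")
  }
  stopifnot(abs(sum(grade_dist) - 1) < 1e-9, noise_rate >= 0)
  structure(list(categories = categories, domains = domains,
                 grade_dist = grade_dist, noise_rate = noise_rate,
                 guard_frac = guard_frac, seed = as.integer(seed)),
            class = "tg18_genspec")
}

# sample a numeric strictly on one side of a threshold, guard margin away
samp_above <- function(th, hi, guard) stats::runif(1, th * (1 + guard), hi)
samp_below <- function(lo, th, guard) stats::runif(1, lo, th * (1 - guard))

#' Sample a planted ground-truth configuration
#'
#' @param category disease category key.
#' @param domain clinical domain (`diagnosis`, `treatment`,
#'   `complications`).
#' @param grade_dist planted grade distribution for acute items.
#' @return a list describing the planted diagnosis class, grade, risk,
#'   special conditions and generation mechanisms.
#' @export
plant_ground_truth <- function(category, domain,
                               grade_dist = c(I = 0.4, II = 0.35,
                                              III = 0.25)) {
  acute <- category %in% c("calculous", "acalculous", "complicated")
  risk <- sample(c("low", "high"), 1)
  if (acute) {
    grade <- if (category == "complicated") {
      sample(c("II", "III"), 1, prob = c(0.5, 0.5))
    } else {
      sample(names(grade_dist), 1, prob = grade_dist)
    }
    conditions <- if (category == "complicated") {
      sample(c("emphysematous", "gangrenous", "perforated"), 1)
    } else character(0)
    g2_mech <- if (grade == "II" && category != "complicated") {
      sample(c("wbc", "duration", "mass"), 1)
    } else NA_character_
    g3_systems <- if (grade == "III") {
      sample(c("cardiovascular", "neurological", "respiratory", "renal",
               "hepatic", "hematological"), sample(1:3, 1))
    } else character(0)
    list(category = category, domain = domain, diagnosis = "definite",
         grade = grade, risk = risk, conditions = conditions,
         g2_mech = g2_mech, g3_systems = g3_systems)
  } else if (category == "mirizzi") {
    fistula <- sample(c(TRUE, FALSE), 1)
    list(category = category, domain = domain, diagnosis = "definite",
         grade = "I", risk = risk, conditions = "mirizzi",
         mirizzi_fistula = fistula, g2_mech = NA_character_,
         g3_systems = character(0))
  } else if (category == "polyps") {
    big <- sample(c(TRUE, FALSE), 1)
    list(category = category, domain = domain,
         diagnosis = "not-cholecystitis", grade = NA_character_, risk = risk,
         conditions = if (big) "carcinoma-suspect" else character(0),
         polyp_big = big, g2_mech = NA_character_, g3_systems = character(0))
  } else if (category == "carcinoma") {
    list(category = category, domain = domain,
         diagnosis = "not-cholecystitis", grade = NA_character_, risk = risk,
         conditions = "carcinoma-suspect", g2_mech = NA_character_,
         g3_systems = character(0))
  } else if (category == "postchole") {
    list(category = category, domain = domain,
         diagnosis = "not-cholecystitis", grade = NA_character_, risk = risk,
         conditions = "bile-duct-injury",
         strasberg = sample(c("A", "D", "E"), 1), g2_mech = NA_character_,
         g3_systems = character(0))
  } else { # chronic_biliary
    list(category = category, domain = domain,
         diagnosis = "not-cholecystitis", grade = NA_character_, risk = risk,
         conditions = character(0), g2_mech = NA_character_,
         g3_systems = character(0))
  }
}

fmt_thous <- function(x) formatC(round(x), format = "d", big.mark = ",")
fmt1 <- function(x) formatC(x, format = "f", digits = 1)
.roman <- c("I", "II", "III", "IV", "V", "VI")

.noise_pool <- c(
  "The patient reports seasonal allergies.",
  "Past surgical history includes appendectomy in childhood.",
  "Electrocardiogram shows normal sinus rhythm.",
  "Mild intermittent headaches are reported.",
  "The patient is a lifelong non-smoker.")

validate_planted <- function(planted) {
  if (!is.na(planted$grade) && planted$grade == "III" &&
      length(planted$g3_systems) == 0L) {
    abort_tg18("planted Grade III requires at least one organ-dysfunction system",
               "tg18_validation_error")
  }
  if (identical(planted$grade, "I") && length(intersect(
    planted$conditions, c("emphysematous", "gangrenous", "perforated")))) {
    abort_tg18("planted Grade I is inconsistent with marked local inflammation",
               "tg18_validation_error")
  }
  if (identical(planted$diagnosis, "not-cholecystitis") &&
      !is.na(planted$grade)) {
    abort_tg18("severity grade cannot be planted without cholecystitis",
               "tg18_validation_error")
  }
  invisible(planted)
}

#' Generate one synthetic vignette from a planted configuration
#'
#' Narrative and question are rendered from templates; laboratory and
#' imaging values are drawn strictly inside or outside each rule threshold
#' according to the planted labels, with a guard margin. The gold option's
#' text is rendered from the canonical phrasing tables so it is consistent
#' with the planted conclusions.
#'
#' @param category disease category key.
#' @param planted output of [plant_ground_truth()].
#' @param seed integer seed.
#' @param noise_rate expected count of irrelevant-finding sentences.
#' @param guard_frac guard margin fraction (see [generation_spec()]).
#' @param id item id.
#' @return a `tg18_vignette` with attribute `truth` (the planted labels,
#'   including the gold option).
#' @export
generate_vignette <- function(category, planted, seed, noise_rate = 0,
                              guard_frac = 0.05, id = "item") {
  validate_planted(planted)
  with_seed(seed, {
    g <- guard_frac
    age <- sample(30:85, 1)
    sex <- sample(c("male", "female"), 1)
    sent <- character(0)
    vals <- list()
    acute <- planted$diagnosis %in% c("definite", "suspected")

    cci <- if (planted$risk == "low") sample(0:5, 1) else sample(6:10, 1)
    asa <- if (planted$risk == "low") sample(1:2, 1) else sample(3:5, 1)
    # high risk only needs one bound broken; sometimes break via ASA only
    if (planted$risk == "high" && stats::runif(1) < 0.5) cci <- sample(0:5, 1)

    if (acute) {
      dur <- if (identical(planted$g2_mech, "duration")) {
        round(samp_above(72, 150, g))
      } else round(stats::runif(1, 24, 72 * (1 - g)))
      wbc <- if (identical(planted$g2_mech, "wbc")) {
        samp_above(18000, 26000, g)
      } else stats::runif(1, 10000 * (1 + g), 18000 * (1 - g))
      crp <- samp_above(3, 25, g)
      temp <- samp_above(38, 40.4, g)
      creat <- if ("renal" %in% planted$g3_systems) {
        samp_above(2, 4.5, g)
      } else samp_below(0.6, 2, g)
      plt <- if ("hematological" %in% planted$g3_systems) {
        samp_below(30000, 100000, g)
      } else stats::runif(1, 150000, 380000)

      sent <- c(sent, sprintf(
        "A %d-year-old %s presents with right upper quadrant pain for %d hours.",
        age, sex, dur))
      exam <- "Physical examination reveals Murphy's sign and right upper quadrant tenderness."
      if (identical(planted$g2_mech, "mass")) {
        exam <- paste(exam,
                      "A palpable tender mass is noted in the right upper quadrant.")
      }
      sent <- c(sent, exam)
      sent <- c(sent, sprintf("Temperature %s °C.", fmt1(temp)))
      if ("cardiovascular" %in% planted$g3_systems) {
        sent <- c(sent, sprintf(
          "Blood pressure is %d/%d mmHg requiring norepinephrine infusion.",
          sample(70:88, 1), sample(40:55, 1)))
      }
      if ("neurological" %in% planted$g3_systems) {
        sent <- c(sent, "The patient is confused.")
      }
      labs <- sprintf(
        "Laboratory findings show WBC %s/μL, CRP %s mg/dL, creatinine %s mg/dL, and platelet count %s/μL.",
        fmt_thous(wbc), fmt1(crp), fmt1(creat), fmt_thous(plt))
      if ("hepatic" %in% planted$g3_systems) {
        labs <- paste(labs, sprintf("PT-INR %s.", fmt1(samp_above(1.5, 3.2, g))))
      }
      if ("respiratory" %in% planted$g3_systems) {
        labs <- paste(labs, sprintf("PaO2/FiO2 ratio %d.",
                                    round(samp_below(120, 300, g))))
      }
      sent <- c(sent, labs)
      if (planted$diagnosis == "definite") {
        stones <- if (category == "acalculous") {
          "No gallstones are identified"
        } else "and multiple gallstones are seen"
        img <- sprintf(
          "Ultrasound demonstrates gallbladder wall thickening of %s mm with pericholecystic fluid; %s.",
          fmt1(samp_above(4, 9, g)), stones)
        if ("emphysematous" %in% planted$conditions) {
          img <- paste(img, "CT shows intramural gas.")
        }
        if ("gangrenous" %in% planted$conditions) {
          img <- paste(img,
                       "There is irregular gallbladder wall thickening with areas of discontinuity.")
        }
        if ("perforated" %in% planted$conditions) {
          img <- paste(img,
                       "CT shows gallbladder perforation with biliary peritonitis.")
        }
        if ("mirizzi" %in% planted$conditions) {
          fist <- if (isTRUE(planted$mirizzi_fistula)) {
            " and a cholecystobiliary fistula"
          } else ""
          img <- paste(img, sprintf(
            "MRCP shows extrinsic compression of the common hepatic duct by an impacted stone in the gallbladder neck%s.",
            fist))
        }
        sent <- c(sent, img)
      }
    } else {
      # non-acute presentations: local symptoms without systemic inflammation
      wbc <- samp_below(5000, 10000, g)
      crp <- samp_below(0.2, 3, g)
      opener <- switch(category,
        chronic_biliary = sprintf(
          "A %d-year-old %s reports recurrent postprandial right upper quadrant pain over several months.",
          age, sex),
        polyps = sprintf(
          "A %d-year-old %s is evaluated for an incidental gallbladder finding.",
          age, sex),
        carcinoma = sprintf(
          "A %d-year-old %s presents with weight loss and vague right upper quadrant pain.",
          age, sex),
        postchole = sprintf(
          "A %d-year-old %s presents ten days after laparoscopic cholecystectomy with abdominal distension.",
          age, sex))
      sent <- c(sent, opener)
      sent <- c(sent, sprintf(
        "Laboratory findings show WBC %s/μL and CRP %s mg/dL.",
        fmt_thous(wbc), fmt1(crp)))
      img <- switch(category,
        chronic_biliary =
          "Ultrasound shows gallstones with a thin gallbladder wall.",
        polyps = sprintf("Ultrasound shows a %s mm gallbladder polyp.",
                         fmt1(if (isTRUE(planted$polyp_big)) {
                           samp_above(10, 16, g)
                         } else samp_below(4, 10, g))),
        carcinoma =
          "CT shows an infiltrative gallbladder mass with liver invasion.",
        postchole = switch(planted$strasberg,
          A = "Imaging and drain output indicate a bile leak from the cystic duct stump.",
          D = "ERCP demonstrates a lateral injury to the extrahepatic bile duct.",
          E = "MRCP demonstrates complete transection of the common hepatic duct."))
      sent <- c(sent, img)
    }
    sent <- c(sent, sprintf("CCI score is %d and ASA-PS is %s.", cci,
                            .roman[asa]))
    n_noise <- stats::rpois(1, noise_rate)
    if (n_noise > 0) {
      sent <- c(sent, sample(.noise_pool, min(n_noise, length(.noise_pool))))
    }
    text <- paste(sent, collapse = " ")

    qa <- render_question(planted)
    letters5 <- LETTERS[1:5]
    pos <- sample(letters5, 1)
    distract <- setdiff(qa$options, qa$gold_text)[1:4]
    opts <- stats::setNames(character(5), letters5)
    opts[pos] <- qa$gold_text
    opts[setdiff(letters5, pos)] <- distract
    vg <- clinical_vignette(id = id, text = text, question = qa$question,
                            options = opts, gold = pos,
                            category = category, domain = planted$domain)
    truth <- planted
    truth$gold <- pos
    truth$cci <- cci
    truth$asa_ps <- asa
    attr(vg, "truth") <- truth
    vg
  })
}

# option pools keyed by planted labels; the gold text realizes the planted
# conclusion through the canonical phrase table so the symbolic agent's
# matching is testable independently of free-text variety
render_question <- function(planted) {
  grade_word <- c(I = "mild", II = "moderate", III = "severe")
  acute <- planted$diagnosis %in% c("definite", "suspected")
  mgmt_text <- c(
    early_lap_chole_72h =
      "Early laparoscopic cholecystectomy within 72 h of symptom onset",
    early_lap_chole_expert =
      "Early laparoscopic cholecystectomy by an experienced surgeon",
    drainage_then_delayed =
      "Medical treatment and percutaneous gallbladder drainage, followed by delayed cholecystectomy",
    organ_support_urgent_drainage =
      "Organ support, antibiotics, and urgent percutaneous cholecystostomy",
    conservative_then_elective =
      "Antibiotics and supportive care, with elective cholecystectomy after risk optimization")
  action_for <- function(grade, risk) {
    if (grade == "III") "organ_support_urgent_drainage"
    else if (grade == "II" && risk == "low") "early_lap_chole_expert"
    else if (grade == "II") "drainage_then_delayed"
    else if (risk == "low") "early_lap_chole_72h"
    else "conservative_then_elective"
  }
  cond_label <- c(
    emphysematous = "Emphysematous cholecystitis",
    gangrenous = "Gangrenous cholecystitis",
    perforated = "Gallbladder perforation with biliary peritonitis",
    mirizzi = "Mirizzi syndrome",
    `carcinoma-suspect` = "Gallbladder carcinoma",
    `bile-duct-injury` = "Bile duct injury")

  if (planted$domain == "diagnosis") {
    question <- "What is the most appropriate diagnostic classification?"
    if (acute) {
      gold <- sprintf("%s acute cholecystitis, Grade %s (%s)",
                      tools::toTitleCase(planted$diagnosis), planted$grade,
                      grade_word[[planted$grade]])
      if (length(planted$conditions) &&
          planted$conditions[1] %in% c("emphysematous", "gangrenous",
                                       "perforated")) {
        gold <- paste0(gold, ", ", tolower(
          cond_label[[planted$conditions[1]]]))
      }
      if ("mirizzi" %in% planted$conditions) {
        gold <- "Mirizzi syndrome with acute cholecystitis"
      }
      others <- setdiff(c("I", "II", "III"), planted$grade)
      pool <- c(gold,
                sprintf("Definite acute cholecystitis, Grade %s (%s)",
                        others, grade_word[others]),
                "Acute cholangitis", "Acute biliary pancreatitis",
                "Peptic ulcer disease")
    } else {
      gold <- switch(planted$category,
        chronic_biliary = "Symptomatic cholelithiasis (biliary colic)",
        polyps = if (isTRUE(planted$polyp_big)) {
          "Gallbladder polyp with features suspicious for carcinoma"
        } else "Benign gallbladder polyp",
        carcinoma = "Gallbladder carcinoma",
        postchole = sprintf("Bile duct injury, Strasberg type %s",
                            planted$strasberg))
      pool <- c(gold, "Acute cholangitis", "Chronic pancreatitis",
                "Peptic ulcer disease", "Adenomyomatosis",
                "Functional dyspepsia")
    }
  } else if (planted$domain == "treatment") {
    question <- "What is the most appropriate initial management?"
    if (acute && !is.na(planted$grade)) {
      act <- action_for(planted$grade, planted$risk)
      gold <- mgmt_text[[act]]
      pool <- c(gold, unname(mgmt_text[setdiff(names(mgmt_text), act)]),
                "Emergency laparoscopic cholecystectomy",
                "Observation with analgesia alone")
    } else {
      gold <- switch(planted$category,
        chronic_biliary = "Outpatient laparoscopic cholecystectomy on a planned basis",
        polyps = if (isTRUE(planted$polyp_big)) {
          "Cholecystectomy for a polyp with suspicious features"
        } else "Ultrasound surveillance at 6 to 12 months",
        carcinoma = "Radical cholecystectomy with regional lymphadenectomy",
        postchole = switch(planted$strasberg,
          A = "Endoscopic retrograde cholangiography with biliary stenting",
          D = "Endoscopic stenting and drain placement",
          E = "Roux-en-Y hepaticojejunostomy at a hepatobiliary centre"))
      pool <- c(gold, "Observation with analgesia alone",
                "Intravenous antibiotics and reassessment",
                "Diagnostic laparoscopy",
                "Referral for external beam radiotherapy",
                "Emergency laparotomy")
    }
  } else { # complications
    question <- "Which complication or special condition best fits this presentation?"
    if (length(planted$conditions)) {
      gold <- cond_label[[planted$conditions[1]]]
      if (planted$conditions[1] == "mirizzi") {
        gold <- sprintf("Mirizzi syndrome, Csendes type %s",
                        if (isTRUE(planted$mirizzi_fistula)) "II" else "I")
      }
      if (planted$conditions[1] == "bile-duct-injury") {
        gold <- sprintf("Bile duct injury, Strasberg type %s",
                        planted$strasberg)
      }
    } else {
      gold <- if (acute) {
        sprintf("No special condition: uncomplicated Grade %s (%s) disease",
                planted$grade, grade_word[[planted$grade]])
      } else switch(planted$category,
        chronic_biliary = "Recurrent biliary colic with risk of acute cholecystitis",
        polyps = "Interval growth requiring surveillance",
        "Disease progression")
    }
    pool <- c(gold, unname(cond_label), "Pericholecystic abscess",
              "Choledocholithiasis", "Acute pancreatitis",
              "Postoperative ileus")
    pool <- unique(pool)
  }
  # drop distractors that would collide with the planted conclusions under
  # concept matching (keeps the gold option the unique best match)
  planted_concepts <- c(
    if (acute) paste0("dx:", planted$diagnosis),
    if (!is.na(planted$grade)) paste0("grade:", planted$grade),
    if (acute && !is.na(planted$grade))
      paste0("action:", action_for(planted$grade, planted$risk)),
    paste0("cond:", planted$conditions))
  tbl <- concept_phrases()
  ok <- vapply(pool, function(opt) {
    if (identical(opt, gold)) return(TRUE)
    !any(vapply(planted_concepts, function(cc) {
      !is.null(tbl[[cc]]) && phrase_hits(opt, tbl[[cc]])
    }, logical(1)))
  }, logical(1))
  pool <- pool[ok]
  pool <- unique(c(gold, pool))
  if (length(pool) < 5L) {
    pool <- c(pool, setdiff(c("Acute appendicitis", "Right lower lobe pneumonia",
                              "Nephrolithiasis", "Mesenteric ischemia"),
                            pool))
  }
  list(question = question, gold_text = gold, options = pool[1:5])
}

#' Generate a stratified question bank with planted ground truth
#'
#' @param spec a [generation_spec()].
#' @return list of class `tg18_bank` with `items` (list of vignettes) and
#'   `truth` (data.frame of planted labels and gold answers).
#' @export
generate_question_bank <- function(spec) {
  stopifnot(inherits(spec, "tg18_genspec"))
  n <- sum(spec$categories)
  with_seed(spec$seed, {
    cats <- sample(rep(names(spec$categories), spec$categories))
    doms <- sample(rep(names(spec$domains), spec$domains))
    item_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    items <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      planted <- plant_ground_truth(cats[i], doms[i], spec$grade_dist)
      id <- sprintf("q%02d", i)
      items[[i]] <- generate_vignette(cats[i], planted, seed = item_seeds[i],
                                      noise_rate = spec$noise_rate,
                                      guard_frac = spec$guard_frac, id = id)
      tr <- attr(items[[i]], "truth")
      truth[[i]] <- data.frame(
        item_id = id, category = cats[i], domain = doms[i],
        diagnosis = tr$diagnosis, grade = tr$grade, risk = tr$risk,
        conditions = paste(tr$conditions, collapse = ";"),
        gold = tr$gold, stringsAsFactors = FALSE)
    }
    structure(list(items = stats::setNames(items, vapply(items, `[[`,
                                                         character(1), "id")),
                   truth = do.call(rbind, truth), spec = spec),
              class = "tg18_bank")
  })
}

#' Plant-and-recover audit
#'
#' Assesses every item of a bank with the inference engine and compares the
#' recovered diagnosis class, severity grade and surgical risk with the
#' planted labels.
#'
#' @param bank a `tg18_bank`.
#' @param kg a `tg18_kg`.
#' @return data.frame with planted and recovered labels and a `match`
#'   column; attribute `recovery_rate` gives the fraction of items where all
#'   three labels match.
#' @export
plant_recovery <- function(bank, kg = build_knowledge_graph()) {
  rows <- lapply(seq_along(bank$items), function(i) {
    vg <- bank$items[[i]]
    tr <- bank$truth[i, ]
    a <- assess_vignette(vg, kg)
    same <- function(x, y) (is.na(x) && is.na(y)) || identical(x, y)
    data.frame(item_id = tr$item_id,
               planted_dx = tr$diagnosis, recovered_dx = a$diagnosis_class,
               planted_grade = tr$grade, recovered_grade = a$grade,
               planted_risk = tr$risk, recovered_risk = a$risk_level,
               match = same(tr$diagnosis, a$diagnosis_class) &&
                 same(tr$grade, a$grade) && same(tr$risk, a$risk_level),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "recovery_rate") <- mean(out$match)
  out
}

#' Simulate an expert rater cohort on a question bank
#'
#' Each simulated rater answers each item correctly with its group's
#' accuracy probability, otherwise picks uniformly among the wrong options.
#'
#' @param bank a `tg18_bank`.
#' @param profiles named numeric vector of per-group accuracy probabilities.
#' @param n_per_group raters per group.
#' @param seed integer seed.
#' @return a `tg18_response_matrix`.
#' @export
simulate_expert_cohort <- function(bank, profiles, n_per_group = 10,
                                   seed = 1) {
  stopifnot(all(profiles >= 0 & profiles <= 1), n_per_group >= 1)
  truth <- bank$truth
  n_items <- nrow(truth)
  with_seed(seed, {
    blocks <- lapply(seq_along(profiles), function(gi) {
      gname <- names(profiles)[gi]
      n <- n_per_group * n_items
      rid <- rep(sprintf("%s_%02d", gname, seq_len(n_per_group)),
                 each = n_items)
      gold <- rep(truth$gold, times = n_per_group)
      correct <- stats::runif(n) < profiles[gi]
      # wrong selections: uniform over the four non-gold options
      shift <- sample.int(4L, n, replace = TRUE)
      wrong <- vapply(seq_len(n), function(i) {
        setdiff(LETTERS[1:5], gold[i])[shift[i]]
      }, character(1))
      data.frame(respondent_id = rid, group = gname,
                 item_id = rep(truth$item_id, times = n_per_group),
                 selection = ifelse(correct, gold, wrong),
                 stringsAsFactors = FALSE)
    })
    key <- truth[, c("item_id", "gold", "domain", "category")]
    names(key)[2] <- "key"
    response_matrix(do.call(rbind, blocks), key)
  })
}
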