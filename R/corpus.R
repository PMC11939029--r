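## Synthetic abstract corpora ------------------------------------------------
##
## Medical abstracts follow a stereotyped rhetorical structure: objective,
## methods, results, conclusion. The generator below emulates a labeled
## sentence corpus with that structure: each rhetorical class has a bank of
## sentence templates built from class-typical discourse cues ("aimed to
## investigate", "were randomly assigned", "significantly", "in conclusion")
## whose topic slots are filled from a shared medical vocabulary, so classes
## differ in function words while overlapping heavily in content words --
## the same signal structure a real abstract corpus presents to a classifier.

topic_vocab <- function(language) {
  if (language == "zh") {
    list(
      condition = c(
        "高血压", "2型糖尿病",
        "慢性胃炎", "冠心病",
        "脑梗死", "类风湿关节炎",
        "慢性乙型肝炎", "支气管哮喘",
        "胃癌", "抑郁症", "骨质疏松",
        "偏头痛", "心房颤动",
        "慢性肾病", "消化性溃疡"
      ),
      intervention = c(
        "针刺", "加味中药汤剂",
        "电针联合艾灸",
        "小剂量阿司匹林",
        "认知行为疗法",
        "规范化运动方案",
        "二甲双胍", "中药复方",
        "华法林", "他汀类药物"
      ),
      outcome = c(
        "临床疗效", "血清炎症指标",
        "生活质量", "血糖控制",
        "血脂水平", "症状评分",
        "复发率", "不良反应",
        "肝功能", "骨密度"
      )
    )
  } else {
    list(
      condition = c(
        "hypertension", "type 2 diabetes", "chronic gastritis",
        "coronary heart disease", "cerebral infarction",
        "rheumatoid arthritis", "chronic hepatitis B", "bronchial asthma",
        "gastric cancer", "depression", "osteoporosis", "migraine",
        "atrial fibrillation", "chronic kidney disease", "peptic ulcer"
      ),
      intervention = c(
        "acupuncture", "a modified herbal decoction",
        "electroacupuncture combined with moxibustion", "low-dose aspirin",
        "cognitive behavioural therapy", "a standardised exercise programme",
        "metformin", "a traditional Chinese medicine compound", "warfarin",
        "statin therapy"
      ),
      outcome = c(
        "clinical efficacy", "serum inflammatory markers", "quality of life",
        "blood glucose control", "lipid profiles", "symptom scores",
        "the recurrence rate", "adverse reactions", "liver function",
        "bone mineral density"
      )
    )
  }
}

## Template banks: >= 20 distinct templates per class, as cue x frame grids.
## Slots: {c} condition, {i} intervention, {o} outcome, {n}/{m} group sizes,
## {w} weeks, {p}/{q} percentages.
template_bank <- function(language) {
  if (!language %in% c("en", "zh")) {
    stop("unknown language tag: ", language, " (expected \"en\" or \"zh\")",
         call. = FALSE)
  }
  if (language == "en") {
    obj_cue <- c("This study aimed to", "We aimed to",
                 "The purpose of this study was to",
                 "The present work sought to", "This trial was designed to")
    obj_frame <- c(
      "%s investigate the effect of {i} on {o} in patients with {c}.",
      "%s evaluate the efficacy and safety of {i} for {c}.",
      "%s explore the relationship between {i} and {o} in {c}.",
      "%s assess whether {i} improves {o} in patients with {c}.",
      "%s determine the clinical value of {i} in the management of {c}."
    )
    met_frame <- c(
      "A total of {n} patients with {c} were randomly divided into a treatment group receiving {i} and a control group receiving conventional therapy.",
      "{n} patients with {c} were enrolled and randomly assigned to {i} or standard care for {w} weeks.",
      "Patients with {c} (n={n}) were allocated at random to receive {i}, and {o} was measured at baseline and after {w} weeks.",
      "We recruited {n} participants with {c}; the observation group was treated with {i} while the control group received routine treatment.",
      "In this randomized controlled design, {n} cases of {c} were assigned to {i} or placebo, and {o} was recorded by blinded assessors.",
      "{o} was measured before and after {w} weeks of treatment with {i} in {n} patients with {c} using standardised instruments.",
      "Using a prospective cohort of {n} patients with {c}, the {i} group and the control group were followed for {w} weeks with {o} assessed monthly.",
      "Sixty-four-slice imaging and laboratory panels were collected, and {n} patients with {c} randomised to {i} were compared with {m} controls on {o}.",
      "{n} subjects with {c} were stratified and randomly assigned; the intervention arm received {i} and {o} was evaluated double-blind.",
      "After screening, {n} patients with {c} were randomized 1:1 to {i} versus usual care, with {o} as the primary endpoint measured over {w} weeks.",
      "Eligible patients with {c} ({n} cases) were grouped by random number table into {i} and control arms, and {o} was compared between groups.",
      "A case-control design enrolled {n} patients with {c} treated with {i} and {m} matched controls, with {o} measured at {w} weeks.",
      "Participants with {c} were randomly sampled ({n} cases) and treated with {i}; {o} and safety indicators were monitored throughout.",
      "The trial randomised {n} patients with {c} to {i} plus usual care or usual care alone, assessing {o} at weeks 0 and {w}.",
      "{n} consecutive patients with {c} received {i}; {o} was quantified with validated scales administered by trained raters.",
      "Following baseline assessment, {n} patients with {c} were assigned via computer-generated randomisation to {i}, with {o} re-measured after {w} weeks.",
      "We conducted a multicentre study of {n} patients with {c}, comparing {i} against conventional therapy on {o} over a {w}-week period.",
      "Block randomisation allocated {n} patients with {c} to the {i} arm or the control arm, and investigators blinded to allocation measured {o}.",
      "A crossover protocol exposed {n} patients with {c} to both {i} and placebo in random order, recording {o} at the end of each {w}-week phase.",
      "Data from {n} patients with {c} treated with {i} were analysed, with {o} extracted from structured case report forms.",
      "The cohort comprised {n} patients with {c}; the experimental group was given {i} and both groups were evaluated for {o} after {w} weeks."
    )
    res_frame <- c(
      "After {w} weeks, {o} in the {i} group was significantly better than in the control group (P<.05).",
      "The total effective rate was {p}% in the treatment group versus {q}% in the control group, a significant difference (P<.05).",
      "{o} improved significantly from baseline in patients receiving {i}, while no significant change was observed in controls.",
      "Compared with the control group, the {i} group showed a significant reduction in {o} (P<.01).",
      "At follow-up, {p}% of patients treated with {i} achieved remission of {c}, compared with {q}% of controls.",
      "The observation group showed significantly higher {o} scores than the control group after treatment (P<.05).",
      "{o} decreased by {p}% in the {i} arm versus {q}% under standard care, and the between-group difference was significant.",
      "Significant improvements in {o} were recorded in the {i} group after {w} weeks (P<.05), with no serious adverse events.",
      "Patients with {c} receiving {i} had markedly better {o} than controls, and the incidence of adverse reactions was {q}%.",
      "The difference in {o} between the two groups reached statistical significance after {w} weeks of {i} (P<.01).",
      "Post-treatment {o} was significantly superior in the {i} group, and {p}% of cases in that group were rated clinically improved.",
      "Relative to baseline, {o} rose significantly under {i} while remaining unchanged in the control group of patients with {c}.",
      "The {i} group outperformed controls on {o} at every assessment point, with an overall response rate of {p}%.",
      "Mean {o} differed significantly between groups after the intervention (P<.05), favouring {i} over conventional therapy for {c}.",
      "{p}% of the {i} group versus {q}% of the control group showed improvement in {o}, a statistically significant difference.",
      "Treatment with {i} produced a significant decrease in {o} among patients with {c} (P<.05) without increasing adverse reactions.",
      "After the {w}-week course, {o} was significantly improved in the experimental group compared with controls (P<.01).",
      "The results showed that {o} in patients given {i} was significantly higher than in those given routine care (P<.05).",
      "Among patients with {c}, {i} significantly reduced {o} relative to control, with effect sizes large at {w} weeks.",
      "Both groups improved, but the improvement in {o} with {i} was significantly greater than with standard therapy (P<.05)."
    )
    con_frame <- c(
      "In conclusion, {i} can effectively improve {o} in patients with {c} and is worthy of clinical application.",
      "These findings suggest that {i} is a safe and effective option for the treatment of {c}.",
      "Our results indicate that {i} may enhance {o} in {c}, supporting its wider clinical use.",
      "Taken together, the evidence supports {i} as an adjunct therapy for {c}, improving {o} with few adverse reactions.",
      "In summary, {i} significantly improves {o} in patients with {c} and merits further study in larger trials.",
      "This study demonstrates that {i} offers clinical benefit for {c}, although longer follow-up is needed to confirm durability.",
      "The findings imply that combining {i} with conventional therapy may optimise {o} in the management of {c}.",
      "Overall, {i} appears effective for {c}; its effect on {o} suggests a promising role in routine practice.",
      "We conclude that {i} improves {o} and is well tolerated in patients with {c}.",
      "These data support the clinical value of {i} for {c} and warrant confirmation in multicentre studies.",
      "In brief, {i} shows favourable efficacy on {o} in {c}, and no serious safety concerns emerged.",
      "The present results suggest that {i} could be recommended to improve {o} in patients suffering from {c}.",
      "Collectively, the observations indicate that {i} is beneficial for {c} and may reduce the burden measured by {o}.",
      "In conclusion, the addition of {i} to standard care improves {o} in {c} and deserves clinical promotion.",
      "These results provide preliminary evidence that {i} ameliorates {o} in {c}, pending replication.",
      "Therefore, {i} can be regarded as an effective and safe intervention for {c} with respect to {o}.",
      "The study concludes that {i} has a positive effect on {o} among patients with {c}.",
      "Our findings support further investigation of {i} as a first-line approach to improving {o} in {c}.",
      "To summarise, {i} produced meaningful gains in {o} for patients with {c} and was well accepted.",
      "In light of these results, {i} is a promising strategy for {c} and may improve long-term {o}."
    )
    objective <- as.vector(outer(obj_cue, obj_frame,
                                 function(a, b) sprintf(b, a)))
    list(objective = objective, methods = met_frame,
         results = res_frame, conclusion = con_frame)
  } else {
    z <- function(...) paste0(...)
    obj <- c(
      z("本研究旨在探讨{i}对{c}患者{o}的影响。"),
      z("本文旨在评价{i}治疗{c}的疗效与安全性。"),
      z("目的：观察{i}对{c}患者{o}的改善作用。"),
      z("本研究拟分析{i}与{c}患者{o}之间的关系。"),
      z("目的：探讨{i}应用于{c}的临床价值。"),
      z("本文拟评估{i}能否改善{c}患者的{o}。"),
      z("目的：研究{i}在{c}综合管理中的作用。"),
      z("本研究的目的是考察{i}对{c}患者{o}的干预效果。"),
      z("旨在明确{i}改善{c}患者{o}的作用机制与疗效。"),
      z("目的：探究{i}联合常规治疗对{c}患者{o}的影响。"),
      z("本研究旨在比较{i}与常规疗法对{c}疗效的差异。"),
      z("目的：分析{i}对{c}患者{o}及预后的影响。"),
      z("本文旨在观察{i}治疗{c}的近远期疗效。"),
      z("目的：评价{i}对{c}患者{o}的调节作用。"),
      z("本研究拟探讨{i}防治{c}的可行性及其对{o}的影响。"),
      z("目的：探讨{i}在{c}患者中的应用效果。"),
      z("本文目的在于验证{i}对{c}患者{o}的改善是否优于对照。"),
      z("旨在系统评价{i}治疗{c}的临床疗效及安全性。"),
      z("目的：考察{i}对{c}患者{o}与生活质量的影响。"),
      z("本研究旨在为{i}应用于{c}提供循证依据。")
    )
    met <- c(
      z("将{n}例{c}患者随机分为观察组与对照组，观察组给予{i}，对照组给予常规治疗。"),
      z("纳入{c}患者{n}例，按随机数字表法分组，治疗组接受{i}，疗程{w}周。"),
      z("选取{n}例{c}患者，随机分为两组，治疗前后测定{o}。"),
      z("共纳入{c}患者{n}例，采用前瞻性队列设计，随访{w}周，每月评估{o}。"),
      z("采用随机对照设计，将{n}例{c}患者分为{i}组与安慰剂组，盲法评定{o}。"),
      z("对{n}例{c}患者于治疗前后采用标准量表测定{o}，疗程{w}周。"),
      z("将符合纳入标准的{n}例{c}患者按1∶1随机分配至{i}组或常规治疗组。"),
      z("采用病例对照设计，纳入接受{i}的{c}患者{n}例及匹配对照{m}例，比较{o}。"),
      z("对{n}例{c}患者进行分层随机分组，干预组接受{i}，双盲评估{o}。"),
      z("筛选后将{n}例{c}患者随机分为两组，以{o}为主要结局指标，观察{w}周。"),
      z("采用区组随机法将{n}例{c}患者分配至{i}组或对照组，评估者对分组不知情。"),
      z("连续纳入{c}患者{n}例，均给予{i}治疗，由经培训的评定员量化{o}。"),
      z("基线评估后，{n}例{c}患者经计算机随机序列分配至{i}组，{w}周后复测{o}。"),
      z("本多中心研究纳入{n}例{c}患者，比较{i}与常规疗法在{w}周内对{o}的影响。"),
      z("采用交叉设计，{n}例{c}患者按随机顺序先后接受{i}与安慰剂，每阶段{w}周末记录{o}。"),
      z("回顾分析{n}例接受{i}治疗的{c}患者资料，从结构化病历中提取{o}。"),
      z("队列共{n}例{c}患者，试验组给予{i}，{w}周后评价两组{o}。"),
      z("将{n}例{c}患者按入院顺序随机分组，观察组在常规治疗基础上加用{i}。"),
      z("采用随机、双盲、安慰剂对照方法，对{n}例{c}患者进行{w}周{i}干预并监测{o}。"),
      z("共纳入{n}例{c}患者，随机分为{i}组{m}例与对照组，治疗前后检测{o}及安全性指标。")
    )
    res <- c(
      z("治疗{w}周后，观察组{o}显著优于对照组，差异有统计学意义（P<0.05）。"),
      z("治疗组总有效率为{p}%，高于对照组的{q}%（P<0.05）。"),
      z("与治疗前相比，{i}组{o}明显改善，而对照组无显著变化。"),
      z("与对照组比较，{i}组{o}显著降低（P<0.01）。"),
      z("随访期间，{i}组{p}%的{c}患者达到缓解，对照组为{q}%。"),
      z("治疗后观察组{o}评分显著高于对照组（P<0.05）。"),
      z("{i}组{o}下降{p}%，对照组下降{q}%，组间差异显著。"),
      z("治疗{w}周后，{i}组{o}改善显著（P<0.05），未见严重不良反应。"),
      z("接受{i}的{c}患者{o}明显优于对照组，不良反应发生率为{q}%。"),
      z("{i}治疗{w}周后，两组{o}差异达到统计学显著水平（P<0.01）。"),
      z("治疗后{i}组{o}显著占优，该组{p}%的病例评定为临床改善。"),
      z("与基线相比，{i}组{o}显著升高，而{c}对照组基本持平。"),
      z("{i}组在各评估时点{o}均优于对照组，总应答率为{p}%。"),
      z("干预后两组{o}均值差异显著（P<0.05），{i}优于常规治疗。"),
      z("{i}组{p}%、对照组{q}%的患者{o}改善，差异具有统计学意义。"),
      z("{i}可显著降低{c}患者的{o}（P<0.05），且未增加不良反应。"),
      z("{w}周疗程结束后，试验组{o}改善程度显著优于对照组（P<0.01）。"),
      z("结果显示，接受{i}的患者{o}显著高于接受常规护理者（P<0.05）。"),
      z("在{c}患者中，{i}较对照显著降低{o}，{w}周时效应量较大。"),
      z("两组均有改善，但{i}组{o}的改善幅度显著大于标准治疗组（P<0.05）。")
    )
    con <- c(
      z("综上所述，{i}可有效改善{c}患者的{o}，值得临床推广。"),
      z("研究提示，{i}是治疗{c}安全有效的选择。"),
      z("结果表明，{i}可提高{c}患者的{o}，支持其更广泛的临床应用。"),
      z("总之，{i}作为{c}的辅助疗法可改善{o}，不良反应少。"),
      z("综上，{i}显著改善{c}患者的{o}，值得在更大样本中进一步验证。"),
      z("本研究表明{i}对{c}具有临床获益，但需更长随访以确认其持久性。"),
      z("提示{i}联合常规治疗有助于优化{c}患者的{o}。"),
      z("总体而言，{i}对{c}有效，其对{o}的改善提示良好的应用前景。"),
      z("我们认为，{i}可改善{o}，且在{c}患者中耐受性良好。"),
      z("这些数据支持{i}治疗{c}的临床价值，有待多中心研究进一步证实。"),
      z("简而言之，{i}对{c}患者{o}疗效确切，未见明显安全性问题。"),
      z("本研究提示可推荐{i}用于改善{c}患者的{o}。"),
      z("综合看来，{i}对{c}有益，可减轻以{o}衡量的疾病负担。"),
      z("综上所述，在常规治疗基础上加用{i}可改善{c}患者的{o}，值得推广。"),
      z("结果为{i}改善{c}患者{o}提供了初步证据，有待重复验证。"),
      z("因此，就{o}而言，{i}可视为{c}的有效且安全的干预措施。"),
      z("本研究结论为{i}对{c}患者的{o}具有积极影响。"),
      z("研究结果支持将{i}作为改善{c}患者{o}的一线策略加以进一步研究。"),
      z("概言之，{i}使{c}患者的{o}获得有意义的改善，患者接受度良好。"),
      z("据此，{i}是治疗{c}的有前景策略，有望改善远期{o}。")
    )
    list(objective = obj, methods = met, results = res, conclusion = con)
  }
}

fill_template <- function(template, slots) {
  out <- template
  for (nm in names(slots)) {
    out <- gsub(paste0("{", nm, "}"), slots[[nm]], out, fixed = TRUE)
  }
  out
}

draw_slots <- function(vocab) {
  list(
    c = sample(vocab$condition, 1L),
    i = sample(vocab$intervention, 1L),
    o = sample(vocab$outcome, 1L),
    n = as.character(sample(seq(40L, 240L, by = 2L), 1L)),
    m = as.character(sample(seq(30L, 120L, by = 2L), 1L)),
    w = as.character(sample(c(4L, 6L, 8L, 12L, 16L, 24L), 1L)),
    p = as.character(sample(seq(78L, 97L), 1L)),
    q = as.character(sample(seq(55L, 77L), 1L))
  )
}

#' Generate a synthetic labeled abstract corpus
#'
#' Builds a sentence corpus with the rhetorical structure of medical
#' abstracts. Sentences are grouped into abstracts whose sections appear in
#' the canonical objective, methods, results, conclusion order; each sentence
#' is rendered from a class-specific template bank (at least 20 templates per
#' class, with class-typical discourse cues) with topic slots filled from a
#' seeded shared vocabulary, so rhetorical classes differ mainly in function
#' words while sharing content words. The requested per-class counts are met
#' exactly; optional label noise then reassigns a fraction of labels
#' uniformly to a wrong class without changing the texts.
#'
#' @param counts_per_class Integer vector of length 4: number of sentences
#'   for objective, methods, results and conclusion respectively.
#' @param language `"en"` or `"zh"`.
#' @param label_noise_rate Fraction of labels (rounded down to a count) to
#'   corrupt; default 0.
#' @param seed Integer seed; identical arguments give identical corpora.
#' @return A data frame with columns `text`, `label`, `abstract_id`,
#'   `sentence_index` (0-based position within the abstract), one row per
#'   sentence, of class `c("sentence_corpus", "data.frame")`.
#' @examples
#' corp <- generate_abstract_corpus(c(5, 5, 5, 5), language = "en", seed = 1)
#' table(corp$label)
#' @export
generate_abstract_corpus <- function(counts_per_class,
                                     language = c("en", "zh"),
                                     label_noise_rate = 0,
                                     seed = 1L) {
  language <- match.arg(language)
  if (length(counts_per_class) != 4L || any(!is.finite(counts_per_class)) ||
      any(counts_per_class < 0) ||
      any(counts_per_class != round(counts_per_class))) {
    stop("`counts_per_class` must be 4 non-negative integers", call. = FALSE)
  }
  counts_per_class <- as.integer(counts_per_class)
  if (sum(counts_per_class) == 0L) {
    stop("all class counts are zero; nothing to generate", call. = FALSE)
  }
  check_scalar(label_noise_rate, "label_noise_rate", 0, 1)
  bank <- template_bank(language)
  if (any(lengths(bank) == 0L)) stop("empty template bank", call. = FALSE)
  vocab <- topic_vocab(language)

  with_seed(seed, {
    remaining <- counts_per_class
    chunks <- list()
    abstract_no <- 0L
    while (sum(remaining) > 0L) {
      abstract_no <- abstract_no + 1L
      aid <- sprintf("a%05d", abstract_no)
      ## one topic per abstract: all sections talk about the same study
      slots <- draw_slots(vocab)
      a_text <- character(0)
      a_label <- character(0)
      for (ci in seq_along(RHET_CLASSES)) {
        if (remaining[ci] == 0L) next
        take <- min(remaining[ci], sample.int(3L, 1L))
        tmpl <- sample(bank[[ci]], take)
        a_text <- c(a_text, vapply(tmpl, fill_template, character(1),
                                   slots = slots, USE.NAMES = FALSE))
        a_label <- c(a_label, rep(RHET_CLASSES[ci], take))
        remaining[ci] <- remaining[ci] - take
      }
      chunks[[abstract_no]] <- list(text = a_text, label = a_label,
                                    aid = aid, n = length(a_text))
    }
    corp <- data.frame(
      text = unlist(lapply(chunks, `[[`, "text"), use.names = FALSE),
      label = unlist(lapply(chunks, `[[`, "label"), use.names = FALSE),
      abstract_id = rep(vapply(chunks, `[[`, character(1), "aid"),
                        vapply(chunks, `[[`, integer(1), "n")),
      sentence_index = unlist(lapply(chunks, function(ch) {
        seq_len(ch$n) - 1L
      }), use.names = FALSE),
      stringsAsFactors = FALSE
    )
    n_noise <- floor(label_noise_rate * nrow(corp))
    if (n_noise > 0L) {
      flip <- sample.int(nrow(corp), n_noise)
      for (j in flip) {
        wrong <- setdiff(RHET_CLASSES, corp$label[j])
        corp$label[j] <- sample(wrong, 1L)
      }
    }
    class(corp) <- c("sentence_corpus", "data.frame")
    corp
  })
}

#' Light paraphrases for duplicate-pair construction
#'
#' Produces, for each input sentence, a lightly edited variant expressing the
#' same content (a discourse-level prefix in the corpus language). Pairs of
#' (sentence, paraphrase) serve as duplicate pairs for autoencoder training.
#'
#' @param texts Character vector of sentences.
#' @param language `"en"` or `"zh"`.
#' @param seed Integer seed selecting among the paraphrase rules.
#' @return Character vector of the same length.
#' @export
paraphrase_sentences <- function(texts, language = c("en", "zh"), seed = 1L) {
  language <- match.arg(language)
  prefixes <- if (language == "zh") {
    c("总体而言，", "据报道，",
      "值得注意的是，")
  } else {
    c("Overall, ", "Notably, ", "As reported, ")
  }
  with_seed(seed, {
    pick <- sample.int(length(prefixes), length(texts), replace = TRUE)
    paste0(prefixes[pick], texts)
  })
}

#' Split a corpus into disjoint train and test sets by abstract
#'
#' Abstracts are atomic: no abstract straddles the split, preventing leakage
#' of near-duplicate sentences between train and test.
#'
#' @param corpus A `sentence_corpus` data frame.
#' @param train_fraction,test_fraction Positive fractions summing to 1.
#' @param seed Integer seed for the abstract-level shuffle.
#' @return A list with elements `train` and `test`, both `sentence_corpus`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.8,
                         test_fraction = 1 - train_fraction, seed = 1L) {
  stopifnot(is.data.frame(corpus))
  check_scalar(train_fraction, "train_fraction")
  check_scalar(test_fraction, "test_fraction")
  if (train_fraction <= 0 || test_fraction <= 0 ||
      abs(train_fraction + test_fraction - 1) > 1e-8) {
    stop("fractions must be positive and sum to 1", call. = FALSE)
  }
  abstracts <- unique(corpus$abstract_id)
  if (length(abstracts) < 2L) {
    stop("need at least 2 abstracts to split", call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- sample(abstracts)
    n_train <- round(train_fraction * length(abstracts))
    n_train <- max(1L, min(length(abstracts) - 1L, n_train))
    train_ids <- shuffled[seq_len(n_train)]
    is_train <- corpus$abstract_id %in% train_ids
    out <- list(
      train = corpus[is_train, , drop = FALSE],
      test = corpus[!is_train, , drop = FALSE]
    )
    out$train <- structure(out$train,
                           class = c("sentence_corpus", "data.frame"))
    out$test <- structure(out$test,
                          class = c("sentence_corpus", "data.frame"))
    rownames(out$train) <- NULL
    rownames(out$test) <- NULL
    out
  })
}

#' @export
print.sentence_corpus <- function(x, ...) {
  cat(sprintf("Sentence corpus: %d sentences, %d abstracts\n",
              nrow(x), length(unique(x$abstract_id))))
  if ("label" %in% names(x) && !all(is.na(x$label))) {
    tab <- table(factor(x$label, levels = RHET_CLASSES))
    cat("  per class:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}
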