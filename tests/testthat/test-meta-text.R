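# Expected stems are the worked examples published with the Porter (1980)
# algorithm, plus domain words traced through the rules by hand.
test_that("the stemmer reproduces the published Porter examples", {
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", cats = "cat",
    feed = "feed", agreed = "agre", plastered = "plaster", bled = "bled",
    motoring = "motor", sing = "sing", conflated = "conflat",
    troubled = "troubl", sized = "size", hopping = "hop", tanned = "tan",
    falling = "fall", hissing = "hiss", fizzed = "fizz", failing = "fail",
    filing = "file", happy = "happi", sky = "sky",
    relational = "relat", conditional = "condit", rational = "ration",
    digitizer = "digit", radically = "radic", differently = "differ",
    analogously = "analog", vietnamization = "vietnam",
    predication = "predic", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope", callousness = "callous",
    formality = "formal", sensitivity = "sensit", sensibility = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electricity = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", communism = "commun", activate = "activ",
    angularity = "angular", homologous = "homolog", effective = "effect",
    probate = "probat", rate = "rate", cease = "ceas",
    controlling = "control", rolling = "roll",
    decision = "decis", decisions = "decis", accumulation = "accumul",
    cognitive = "cognit", memory = "memori", memories = "memori")
  got <- porter_stem(names(pairs))
  expect_equal(got, unname(pairs))
})

test_that("inflected forms collapse onto one stem", {
  expect_equal(porter_stem("decisions"), porter_stem("decision"))
  expect_equal(porter_stem("memories"), porter_stem("memory"))
  expect_equal(porter_stem("responses"), porter_stem("response"))
})

test_that("term assignment requires the stemmed form in the text", {
  texts <- c(a1 = "Fast decisions under uncertainty in the human brain",
             a2 = "Working memory maintenance of decision variables",
             a3 = "A study of working memories and attention")
  db <- build_term_db(texts, c("decision", "working memory", "attention"),
                      min_articles = 1)
  expect_true("decision" %in% db$articles$a1)   # matched via "decisions"
  expect_true("decision" %in% db$articles$a2)
  expect_false("decision" %in% db$articles$a3)
  # two-word term matches consecutive stemmed tokens, across inflection
  expect_true("working memory" %in% db$articles$a2)
  expect_true("working memory" %in% db$articles$a3)
  expect_false("working memory" %in% db$articles$a1)
})

test_that("rare and excluded terms are removed from the database", {
  texts <- setNames(c(rep("perceptual decision making task", 15),
                      rep("attention and faces in pictures", 14)),
                    sprintf("a%02d", 1:29))
  db <- build_term_db(texts, c("decision", "attention", "picture", "face"),
                      min_articles = 15)
  expect_true("decision" %in% db$terms)
  expect_false("attention" %in% db$terms)  # present in only 14 articles
  expect_false("picture" %in% db$terms)    # excluded list
  expect_false("face" %in% db$terms)       # excluded via the face* pattern
  expect_error(build_term_db(texts, character()), "empty term list")
  expect_error(build_term_db(character(), "decision"), "empty article")
})

test_that("stop words are filtered before matching", {
  sw <- stop_words()
  expect_true(all(c("the", "of", "and", "end") %in% sw))
  toks <- accumaint:::tokenize_text("the decision of the end")
  expect_false(any(c("the", "of", "end") %in% toks))
})
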