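# Generates the packaged personal-name lists (inst/extdata/*.txt).
# The lists are small open stand-ins for the large commercial name databases
# used in production deployments: common English given names and surnames,
# expanded with informal forms (diminutives) and systematic misspellings
# (single dropped vowels, e.g. Bill -> Bll), minus any word that collides
# with the other packaged resources or with common sentence-initial words.
# Run from the package root: Rscript data-raw/make_name_lists.R

female <- c(
  "mary", "patricia", "linda", "barbara", "elizabeth", "jennifer", "maria",
  "susan", "margaret", "dorothy", "lisa", "nancy", "karen", "betty", "sandra",
  "donna", "carol", "ruth", "sharon", "michelle", "laura", "sarah", "kimberly",
  "deborah", "jessica", "shirley", "cynthia", "angela", "melissa", "brenda",
  "amy", "anna", "rebecca", "kathleen", "pamela", "martha", "debra", "amanda",
  "stephanie", "carolyn", "christine", "marie", "janet", "catherine", "frances",
  "ann", "joyce", "diane", "alice", "julie", "heather", "teresa", "doris",
  "gloria", "evelyn", "jean", "cheryl", "mildred", "katherine", "joan",
  "ashley", "judith", "rose", "janice", "kelly", "nicole", "judy", "christina",
  "kathy", "theresa", "beverly", "denise", "tammy", "irene", "jane", "lori",
  "rachel", "marilyn", "andrea", "kathryn", "louise", "sara", "anne", "jacqueline",
  "wanda", "bonnie", "julia", "ruby", "lois", "tina", "phyllis", "norma",
  "paula", "diana", "annie", "lillian", "emily", "robin", "peggy", "crystal",
  "gladys", "rita", "dawn", "connie", "florence", "tracy", "edna", "tiffany",
  "carmen", "rosa", "cindy", "monica", "sheila", "ethel", "ellen", "elaine",
  "marjorie", "carrie", "charlotte", "bertha", "pauline", "josephine", "lucille",
  "gail", "leila", "wendy", "vanessa", "valerie", "yvonne", "hazel", "lauren",
  "esther", "vivian", "lena", "lucy", "edith", "kristen", "megan", "colleen",
  "allison", "suzanne", "beatrice", "michele", "vera", "kara", "natalie",
  "agnes", "veronica", "jill", "erica", "geraldine", "cathy", "joanne",
  "shannon", "sherry", "eleanor", "priscilla", "meredith", "gwendolyn",
  "yolanda", "maureen", "greta", "ingrid", "fatima", "amina", "priya", "mei",
  "yuki", "sofia", "isabella", "camila", "valentina", "noor", "zainab",
  "keisha", "latoya", "aaliyah", "svetlana", "natasha", "olga", "irina",
  "dolores", "esmeralda", "guadalupe", "rosario", "magdalena", "bridget",
  "siobhan", "astrid", "freya", "marta", "katarina", "elena", "dina"
)

male <- c(
  "james", "john", "robert", "michael", "william", "david", "richard",
  "charles", "joseph", "thomas", "christopher", "daniel", "paul", "donald",
  "kenneth", "steven", "edward", "brian", "ronald", "anthony", "kevin",
  "jason", "matthew", "gary", "timothy", "jose", "larry", "jeffrey", "stephen",
  "scott", "eric", "andrew", "raymond", "gregory", "joshua", "jerry", "dennis",
  "walter", "patrick", "peter", "harold", "douglas", "henry", "carl", "arthur",
  "ryan", "roger", "joe", "juan", "gerald", "albert", "willie", "jonathan",
  "harry", "ralph", "roy", "eugene", "bobby", "russell", "louis", "philip",
  "johnny", "nathan", "benjamin", "bruce", "adam", "samuel", "leonard",
  "alfred", "bernard", "vincent", "norman", "herbert", "frederick", "clarence",
  "leroy", "marvin", "theodore", "clifford", "miguel", "oscar", "jaime",
  "cesar", "andres", "rodolfo", "meehai", "dimitri", "sergei", "ivan",
  "vladimir", "ahmed", "hassan", "omar", "tariq", "rajesh", "sanjay", "arjun",
  "wei", "hiroshi", "kenji", "giovanni", "marco", "lorenzo", "pablo", "diego",
  "fernando", "alejandro", "ricardo", "eduardo", "stefan", "klaus", "gunter",
  "lars", "erik", "sven", "nils", "pierre", "jacques", "luc", "etienne",
  "antoine", "seamus", "declan", "lachlan", "magnus", "viktor", "milos",
  "janusz", "piotr", "tomas", "pavel", "andrei", "nikolai", "yusuf", "karim",
  "abdul", "ismail", "rashid", "jamal", "malik", "darnell", "tyrone",
  "maurice", "cedric", "wallace", "dwight", "clyde", "wendell", "errol",
  "gilbert", "horace", "irving", "jasper", "leon", "milton", "orville",
  "percy", "quentin", "rufus", "sylvester", "ulysses", "virgil", "wilbur"
)

last <- c(
  "smith", "johnson", "williams", "brown", "jones", "miller", "davis",
  "garcia", "rodriguez", "wilson", "martinez", "anderson", "taylor", "moore",
  "jackson", "martin", "lee", "perez", "thompson", "harris", "sanchez",
  "clark", "ramirez", "lewis", "robinson", "walker", "hall", "allen",
  "hernandez", "wright", "lopez", "hill", "scott", "green", "adams", "baker",
  "gonzalez", "nelson", "carter", "mitchell", "roberts", "turner", "phillips",
  "campbell", "parker", "evans", "edwards", "collins", "stewart", "morris",
  "rogers", "reed", "cook", "morgan", "bell", "murphy", "bailey", "rivera",
  "cooper", "richardson", "cox", "howard", "ward", "torres", "peterson",
  "gray", "ramos", "watson", "brooks", "kelly", "sanders", "price", "bennett",
  "wood", "barnes", "ross", "henderson", "coleman", "jenkins", "perry",
  "powell", "sullivan", "russell", "ortiz", "jenkinson", "gutierrez", "fisher",
  "simmons", "foster", "bryant", "alexander", "griffin", "hayes", "myers",
  "ford", "hamilton", "graham", "wallace", "woods", "cole", "webb", "tucker",
  "freeman", "burns", "henry", "vasquez", "snyder", "simpson", "crawford",
  "jimenez", "porter", "mason", "shaw", "gordon", "wagner", "hunter",
  "romero", "hicks", "dixon", "palmer", "robertson", "grant", "gardner",
  "payne", "pierce", "dunn", "kennedy", "spencer", "hawkins", "arnold",
  "cruz", "greene", "ferguson", "medina", "nichols", "stephens", "weaver",
  "ryan", "schmidt", "carr", "vargas", "castillo", "wheeler", "chapman",
  "oliver", "montgomery", "richards", "williamson", "johnston", "banks",
  "meyer", "bishop", "mccoy", "howell", "alvarez", "morrison", "hansen",
  "fernandez", "harvey", "little", "burton", "stanley", "nguyen", "george",
  "andrews", "manning", "harper", "kim", "armstrong", "dean", "lawrence",
  "walsh", "munoz", "riley", "lynch", "soto", "weber", "fields", "perkins",
  "hoffman", "carlson", "daniels", "cunningham", "bradley", "lambert",
  "byrd", "reyes", "santos", "fleming", "gallagher", "duncan", "hopkins",
  "cameron", "fletcher", "mckenzie", "sutton", "chambers", "gibbs", "mullins",
  "norton", "pearson", "quinn", "rasmussen", "sherman", "thornton",
  "underwood", "vaughn", "whitaker", "yates", "zimmerman", "abbott",
  "blackwell", "calderon", "donovan", "eastman", "farrell", "goodwin",
  "hubbard", "ingram", "jarvis", "keller", "lindqvist", "mercer", "nolan",
  "osborne", "preston", "quigley", "rowland", "stafford", "tillman",
  "vickers", "wendt", "yoder", "zuniga", "okafor", "patel", "singh", "kaur",
  "chowdhury", "rahman", "haddad", "nakamura", "tanaka", "kobayashi", "chen",
  "wang", "zhang", "liu", "novak", "kowalski", "petrov", "ivanov", "moreau",
  "dubois", "laurent", "rousseau", "bergstrom", "lindgren", "virtanen",
  "korhonen", "jensen", "larsen", "andersen", "olsen", "bakker", "devries",
  "jansen", "visser", "mulder", "peeters", "janssens", "ferrari", "ricci",
  "marino", "greco", "silva", "pereira", "costa", "almeida", "oliveira"
)

# Diminutives and informal forms, keyed by formal name.
diminutives <- c(
  william = "bill billy will willie liam",
  robert = "bob bobby rob robbie bert",
  richard = "dick rick ricky rich",
  james = "jim jimmy jamie",
  john = "jack johnny jon",
  michael = "mike mikey mick",
  david = "dave davy",
  charles = "chuck charlie chas",
  joseph = "joey jos",
  thomas = "tom tommy",
  christopher = "chris kit",
  daniel = "dan danny",
  donald = "don donny",
  kenneth = "ken kenny",
  steven = "steve stevie",
  edward = "ed eddie ted teddy ned",
  anthony = "tony",
  matthew = "matt matty",
  timothy = "tim timmy",
  jeffrey = "jeff",
  stephen = "steph",
  andrew = "andy drew",
  joshua = "josh",
  dennis = "denny",
  patrick = "pat paddy",
  peter = "pete petey",
  douglas = "doug dougie",
  henry = "hank hal",
  arthur = "art artie",
  gerald = "gerry jerry",
  albert = "al bertie",
  jonathan = "jonny",
  ralph = "ralphie",
  eugene = "gene",
  benjamin = "ben benny benji",
  samuel = "sam sammy",
  leonard = "len lenny",
  bernard = "bernie",
  vincent = "vince vinny",
  herbert = "herb herbie",
  frederick = "fred freddy fritz",
  theodore = "theo",
  gregory = "greg",
  lawrence = "larry lars",
  nicholas = "nick nicky",
  alexander = "alex sandy lex",
  elizabeth = "liz lizzie beth betsy eliza libby",
  margaret = "maggie meg peggy madge marge",
  patricia = "pat patty tricia trish",
  jennifer = "jen jenny",
  susan = "sue susie suzy",
  dorothy = "dot dottie",
  barbara = "barb babs",
  deborah = "deb debbie",
  jessica = "jess jessie",
  cynthia = "cindy",
  rebecca = "becky becca",
  kathleen = "kath kathy katie kay",
  pamela = "pam pammy",
  amanda = "mandy",
  stephanie = "steph steffi",
  christine = "chris christy tina",
  catherine = "cathy cat kate katie kitty",
  frances = "fran frannie",
  jacqueline = "jackie",
  victoria = "vicky tori",
  kimberly = "kim kimmy",
  michelle = "shelly",
  melissa = "mel missy",
  christina = "chrissy",
  katherine = "kathy katya",
  josephine = "josie jo",
  lucille = "lucy lu",
  eleanor = "ellie nell nora",
  gwendolyn = "gwen",
  priscilla = "cilla",
  natalie = "nat",
  veronica = "ronnie",
  suzanne = "suzie",
  charlotte = "lottie charlie",
  emily = "em emmy",
  abigail = "abby gail"
)

# Single-vowel-drop misspellings (Bill -> Bll), at least three characters.
misspellings <- function(names) {
  out <- character(0)
  for (nm in names) {
    chars <- strsplit(nm, "")[[1]]
    vowel_pos <- which(chars %in% c("a", "e", "i", "o", "u"))
    # internal vowels only: keep a recognizable first letter
    vowel_pos <- vowel_pos[vowel_pos > 1]
    for (v in vowel_pos) {
      cand <- paste(chars[-v], collapse = "")
      if (nchar(cand) >= 3) out <- c(out, cand)
    }
  }
  out
}

expand <- function(base, dims = character(0)) {
  informal <- unlist(strsplit(unname(dims[names(dims) %in% base]), " "))
  full <- unique(c(base, informal))
  unique(c(full, misspellings(full)))
}

# Words that must never be treated as names: everything that can occur
# capitalized in ordinary prose or that belongs to another resource.
read_col <- function(path, col = 1) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE, quote = "")
  tolower(unlist(strsplit(as.character(x[[col]]), "[^[:alpha:]']+")))
}
ext <- "inst/extdata"
blocklist <- unique(c(
  readLines(file.path(ext, "stopwords.txt")),
  read_col(file.path(ext, "gazetteer.tsv")),
  read_col(file.path(ext, "health_terms.tsv")),
  tolower(unlist(strsplit(read.delim(file.path(ext, "content_keywords.tsv"),
                                     header = FALSE)$V2, " "))),
  tolower(month.name), tolower(month.abb),
  # common sentence-openers and letter vocabulary
  c("dear", "sincerely", "regards", "thanks", "hope", "grace", "joy", "faith",
    "may", "june", "april", "august", "living", "routine", "gentle", "keeping",
    "many", "plain", "travel", "everyone", "dinner", "miss", "young", "park",
    "white", "black", "king", "knight", "bishop", "stone", "wells", "summer",
    "winter", "autumn", "spring", "daisy", "holly", "ivy", "iris", "dawn",
    "hunter", "mason", "reader", "patient", "questions", "experience",
    "references", "signature", "condition", "profile", "professional",
    "extended", "daytime", "reach", "town", "home", "health", "card",
    "number", "date", "birth", "claim", "prescribed")
))

# surname spelling variants seen in transcription: -son/-sen endings,
# Mc-/Mac- prefixes, collapsed double letters
surname_variants <- function(names) {
  v <- c(
    sub("son$", "sen", names[grepl("son$", names)]),
    sub("sen$", "son", names[grepl("sen$", names)]),
    sub("^mc", "mac", names[grepl("^mc", names)]),
    gsub("(.)\\1", "\\1", names[grepl("(.)\\1", names)])
  )
  v[nchar(v) >= 3]
}

female_x <- sort(setdiff(expand(female, diminutives), blocklist))
male_x <- sort(setdiff(expand(male, diminutives), blocklist))
last_full <- unique(c(last, surname_variants(last)))
last_x <- sort(setdiff(unique(c(last_full, misspellings(last_full))), blocklist))

stopifnot(length(female_x) + length(male_x) >= 1000, length(last_x) >= 1000)
stopifnot(all(c("william", "bill", "billy", "bll", "leila", "meehai") %in%
                c(female_x, male_x)),
          all(c("smith", "johnson") %in% last_x))

writeLines(female_x, file.path(ext, "female_first.txt"), useBytes = TRUE)
writeLines(male_x, file.path(ext, "male_first.txt"), useBytes = TRUE)
writeLines(last_x, file.path(ext, "last_names.txt"), useBytes = TRUE)
cat(sprintf("female %d, male %d, last %d\n",
            length(female_x), length(male_x), length(last_x)))
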