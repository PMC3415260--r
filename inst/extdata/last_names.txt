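abbott
abbtt
abot
abt
adams
adms
alen
alexander
alexandr
alexnder
allen
alln
almeda
almeid
almeida
almida
aln
alvarez
alvarz
alvrez
alxander
andersen
andersn
anderson
andrews
andrsen
andrson
andrws
armstrng
armstrong
arnld
arnold
bailey
baily
baker
bakker
bakkr
bakr
baley
banks
barnes
barns
bel
bell
benet
bennett
benntt
bent
bergstrm
bergstrom
biley
bishp
bker
bkker
blackwel
blackwell
blackwl
blackwll
blckwel
blckwell
bll
bnet
bnks
bnnett
bradley
bradly
brdley
brgstrom
brks
brnes
brns
broks
brooks
brown
brton
brwn
bryant
brynt
bshop
burns
burtn
burton
byrd
caldern
calderon
caldron
camern
cameron
campbel
campbell
campbl
campbll
camron
car
carlsen
carlsn
carlson
carr
carter
cartr
castil
castill
castillo
castilo
castllo
castlo
chambers
chambrs
chapman
chapmn
chen
chmbers
chn
chowdhry
chowdhury
chpman
chwdhury
clark
clderon
cle
cleman
clins
cllins
clrk
cmeron
cmpbel
cmpbell
cningham
cnningham
cok
col
cole
coleman
colemn
colins
collins
collns
colman
colns
cook
cooper
coopr
coper
copr
cost
costa
cox
cper
crawford
crawfrd
crlsen
crlson
crr
crter
cruz
crwford
crz
csta
cstillo
cstilo
cuningham
cuninghm
cunngham
cunningham
cunninghm
cunnngham
dan
danels
daniels
danils
davis
davs
dbois
dean
den
devres
devries
devris
dixn
dixon
dncan
dniels
dnn
dnovan
donovan
donovn
donvan
dubis
dubois
dubos
dun
duncan
duncn
dunn
dvis
dvries
dxon
eastman
eastmn
edwards
edwrds
estman
evans
evns
farel
farl
farrell
farrll
felds
ferar
ferari
fergsen
fergson
fergusen
fergusn
ferguson
fernandez
fernandz
fernndez
ferrar
ferrari
ferri
ferrri
fields
filds
fisher
fishr
fleming
flemng
fletcher
fletchr
flming
fltcher
ford
foster
fostr
frari
frd
freeman
freemn
frel
freman
fremn
frgusen
frguson
frman
frnandez
frrari
frrell
fsher
fster
galagher
galaghr
galgher
gallagher
gallaghr
gallgher
garca
garci
garcia
gardner
gardnr
gbbs
gbs
gdwin
georg
gerge
gibbs
gibs
glagher
gllagher
gnzalez
godwin
godwn
gonzalez
gonzalz
gonzlez
goodwin
goodwn
gordn
gordon
gorge
graham
grahm
grant
gray
grcia
grco
grdner
grdon
grec
greco
green
greene
gren
grene
grffin
grfin
grham
griffin
griffn
grifin
grifn
grn
grne
grnt
gry
gtierez
gtierrez
guterez
guterrez
gutierez
gutierrez
gutierrz
gutierz
gutirez
gutirrez
hadad
hadd
haddad
haddd
hal
hall
hamiltn
hamilton
hamlton
hansen
hansn
hanson
haris
harpr
harris
harrs
hars
harvey
harvy
hawkins
hawkns
hayes
hays
hbard
hbbard
hcks
hdad
hddad
hendersen
hendersn
henderson
hendrsen
hendrson
henry
hernandez
hernandz
hernndez
hffman
hfman
hicks
hil
hill
hll
hmilton
hndersen
hnderson
hnry
hnsen
hnson
hnter
hoffman
hoffmn
hofman
hofmn
hopkins
hopkns
howard
howel
howell
howl
howll
howrd
hpkins
hris
hrnandez
hrper
hrris
hrvey
hubard
hubbard
hubbrd
hubrd
huntr
hward
hwel
hwell
hwkins
hyes
ingram
ingrm
ivanov
ivanv
ivnov
jacksen
jacksn
jackson
jansen
jansens
jansn
jansns
janson
janssens
janssns
jarvis
jarvs
jcksen
jckson
jenkins
jenkinsen
jenkinsn
jenkinson
jenkns
jenknsen
jenknson
jensen
jensn
jenson
jhnsen
jhnson
jhnston
jimenez
jimenz
jimnez
jmenez
jnes
jnkins
jnkinsen
jnkinson
jnsen
jnsens
jnson
jnssens
johnsen
johnsn
johnson
johnstn
johnston
jones
jons
jrvis
kar
kaur
kbayashi
keler
keller
kellr
kelly
kelr
kely
kendy
kenedy
kenndy
kennedy
kim
kler
kller
klly
kly
knedy
knnedy
kobayash
kobayashi
kobayshi
kobyashi
korhnen
korhonen
korhonn
kowalsk
kowalski
kowlski
krhonen
kur
kwalski
lambert
lambrt
larent
larsen
larsn
larson
laurent
laurnt
lawrenc
lawrence
lawrnce
lee
lewis
lews
lindgren
lindgrn
lindqvist
lindqvst
litl
litle
littl
little
liu
lmbert
lndgren
lndqvist
lopez
lopz
lpez
lrsen
lrson
ltle
lttle
lurent
lwis
lwrence
lynch
maccoy
maccy
mackenze
mackenzi
mackenzie
macknzie
maning
manng
manning
mannng
marin
marino
marno
martin
martinez
martinz
martn
martnez
masen
masn
mccoy
mccy
mckenze
mckenzi
mckenzie
mcknzie
mcoy
mcy
mdina
medin
medina
medna
mercer
mercr
meyer
meyr
miler
miller
millr
milr
mitchel
mitchell
mitchl
mitchll
mlder
mler
mlins
mller
mllins
mning
mnning
mnoz
mntgomery
montgmery
montgomery
montgomry
moor
moore
mor
morau
morea
moreau
moreu
morgan
morgn
moris
morisn
morison
morris
morrisen
morrisn
morrison
morrs
morrsen
morrson
mors
morson
mrcer
mre
mreau
mrgan
mrino
mris
mrison
mrphy
mrris
mrrisen
mrrison
mrtin
mrtinez
msen
mson
mtchel
mtchell
mulder
muldr
mulins
mullins
mullns
mulns
munoz
munz
murphy
myer
myers
myrs
nakamra
nakamur
nakamura
nakmura
nchols
nelsen
nelsn
nelson
nguyen
nguyn
ngyen
nichls
nichols
nkamura
nlan
nlsen
nlson
nolan
noln
nortn
norton
novak
novk
nrton
nvak
okafor
okafr
okfor
oliveir
oliveira
oliver
olivera
olivira
olivr
olsen
olsn
olson
olveira
olver
ortiz
ortz
osborn
osborne
osbrne
palmer
palmr
parker
parkr
parsen
parson
patel
patl
payn
payne
pearsen
pearsn
pearson
peeters
peetrs
perce
pereir
pereira
perera
perez
perira
perkins
perkns
perry
persen
person
pery
perz
peters
petersen
petersn
peterson
petrov
petrs
petrsen
petrson
petrv
philips
phillips
phillps
philps
phlips
phllips
pierc
pierce
pirce
plmer
portr
powel
powell
powl
powll
prce
preira
prestn
preston
prez
pric
price
prker
prkins
prry
prston
prter
pry
ptel
pters
ptersen
pterson
ptrov
pwel
pwell
pyne
qigley
qin
qinn
qugley
quigley
quigly
quin
quinn
qun
qunn
rahman
rahmn
ramirez
ramirz
ramos
ramrez
rams
rasmsen
rasmssen
rasmsson
rasmusen
rasmusn
rasmussen
rasmussn
rasmusson
rberts
rbertsen
rbertson
rbinsen
rbinson
rcci
rchards
rchardsen
rchardson
rci
rdriguez
red
reed
reyes
reys
rgers
rhman
ric
ricc
ricci
richards
richardsen
richardsn
richardson
richrds
richrdsen
richrdson
rici
riley
rily
river
rivera
rivra
rley
rmero
rmirez
rmos
roberts
robertsen
robertsn
robertson
robinsen
robinsn
robinson
robnsen
robnson
robrts
robrtsen
robrtson
rodrguez
rodrigez
rodriguez
rodriguz
rogers
rogrs
romer
romero
romro
ros
roseau
ross
rosseau
rousau
rousea
rouseau
rouseu
roussau
roussea
rousseau
rousseu
rowland
rowlnd
rsel
rsmusen
rsmussen
rsmusson
rss
rssell
ruseau
rusel
rusl
russeau
russell
russll
rvera
rwland
ryan
ryes
ryn
sanchez
sanchz
sanders
sandrs
santos
sants
schmdt
schmidt
scot
scott
sct
sctt
shaw
sherman
shermn
shrman
shw
silv
silva
simmns
simmons
simns
simons
simpsen
simpsn
singh
slivan
sllivan
slva
smith
smmons
smons
smpsen
smpson
smth
snchez
snders
sngh
sntos
snyder
snydr
sot
soto
spencer
spencr
spncer
stafford
staffrd
staford
stafrd
stanley
stanly
stephens
stephns
stewart
stewrt
stfford
stford
stnley
sto
ston
stphens
stton
stwart
sulivan
sulivn
sullivan
sullivn
sullvan
sulvan
sutn
suton
suttn
sutton
tanak
tanaka
tanka
taylor
taylr
tcker
thmpsen
thmpson
thompsen
thompsn
thompson
thorntn
thornton
thrnton
tillman
tillmn
tilman
tilmn
tllman
tlman
tnaka
tores
torres
torrs
tors
tres
trner
trres
tucker
tuckr
turner
turnr
tylor
underwd
underwod
underwood
undrwod
undrwood
vaghn
vargas
vargs
vasqez
vasquez
vasquz
vaughn
vckers
vickers
vickrs
virtanen
virtann
virtnen
viser
visr
visser
vissr
vrgas
vrtanen
vser
vsquez
vsser
vughn
wagner
wagnr
walac
walace
walce
walker
walkr
wallac
wallace
wallce
walsh
wang
ward
watsen
watsn
watson
waver
wbb
wber
wds
weaver
weavr
web
webb
weber
webr
wendt
wever
wgner
wheeler
wheelr
wheler
whelr
whitaker
whitakr
whitker
whler
whtaker
wilams
wilamson
wiliams
wiliamsn
wiliamson
wilims
wilimson
willams
willamsen
willamson
williams
williamsen
williamsn
williamson
willims
willimsen
willimson
wilsen
wilsn
wilson
wlace
wliams
wliamson
wlker
wllace
wlliams
wlliamsen
wlliamson
wlsen
wlsh
wlson
wndt
wng
wod
wods
wood
woods
wrd
wrght
wright
wtsen
wtson
yates
yats
yder
yoder
yodr
ytes
zhang
zhng
zimerman
zimermn
zimmerman
zimmermn
zimmrman
zimrman
zmerman
zmmerman
zniga
zunga
zunig
zuniga
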