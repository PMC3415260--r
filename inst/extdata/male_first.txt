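abdl
abdul
adam
adm
ahmd
ahmed
al
albert
albrt
alejandr
alejandro
alejndro
alfrd
alfred
aljandro
andre
andrei
andres
andrew
andri
andrs
andrw
andy
anthny
anthony
antine
antoin
antoine
antone
arjn
arjun
art
arte
arthr
arthur
arti
artie
bbby
ben
benj
benjamin
benjamn
benji
benjmin
benny
bernard
berne
berni
bernie
bernrd
bert
berte
berti
bertie
bill
billy
bll
blly
bnjamin
bnji
bnny
bob
bobby
bran
brce
brian
brin
brnard
brnie
brt
brtie
bruc
bruce
carl
cdric
cedrc
cedric
cesar
cesr
charle
charles
charli
charlie
charls
chas
chck
chris
christopher
christophr
christpher
chrles
chrlie
chrs
chrstopher
chs
chuck
clarenc
clarence
clarnce
clfford
clifford
cliffrd
clrence
clyd
clyde
crl
csar
dan
danel
daniel
danil
danny
darnell
darnll
dav
davd
dave
david
davy
dck
dclan
declan
decln
dego
dennis
denns
denny
dick
dieg
diego
digo
dimitr
dimitri
dimtri
dmitri
dnald
dniel
dnnis
dnny
dog
dogie
doglas
don
donald
donld
donny
doug
douge
dougi
dougie
douglas
dougls
drew
drnell
drw
dug
dugie
duglas
dve
dvid
dvy
dwght
dwight
ed
edardo
edde
eddi
eddie
eduard
eduardo
edurdo
edwrd
egene
erc
eric
erik
erk
errl
errol
etenne
etienn
etienne
etinne
eugen
eugene
eugne
fernand
fernando
fernndo
frd
frddy
frderick
fred
freddy
frederck
frederick
fredrick
fritz
frnando
frtz
gary
gen
gene
gerald
gerld
gerry
gilbert
gilbrt
giovann
giovanni
giovnni
givanni
glbert
gne
gnter
govanni
grald
greg
gregory
gregry
grg
grgory
grry
gry
gunter
guntr
hal
hank
harld
harold
hassan
hassn
henry
herb
herbe
herbert
herbi
herbie
herbrt
hirosh
hiroshi
hirshi
hnk
hnry
horac
horace
horce
hrace
hrb
hrbert
hrbie
hrold
hroshi
hrry
hssan
irving
irvng
ismail
ismal
ismil
ivan
ivn
jack
jacqes
jacques
jacqus
jaim
jaime
jamal
jame
james
jami
jamie
jaml
jams
jansz
janusz
jasn
jason
jaspr
jck
jcques
jeff
jeffrey
jeffry
jerry
jey
jff
jffrey
jhn
jhnny
jim
jime
jimmy
jmal
jmes
jmie
jmmy
jnathan
jnny
jnusz
joe
joey
john
johnny
jon
jonathan
jonathn
jonny
jonthan
jos
jose
joseph
josh
josha
joshu
joshua
josph
jrry
jse
jseph
jsh
jshua
json
jsper
juan
karim
karm
ken
kenj
kenji
kenneth
kennth
kenny
kevin
kevn
kit
klas
klaus
klus
knji
knneth
knny
krim
kvin
lachlan
lachln
lam
larry
lars
lchlan
len
lenard
lenny
leon
leonard
leonrd
leroy
lery
liam
lim
lnny
lois
lon
lonard
lorenz
lorenzo
lornzo
louis
lous
lrenzo
lroy
lrry
lrs
luc
luis
magns
magnus
malik
malk
marc
marco
marice
marvin
marvn
matt
matthew
matthw
matty
maurce
mauric
maurice
mchael
mck
meeha
meehai
meehi
mehai
mgnus
mguel
michael
michal
michel
mick
migel
miguel
migul
mik
mike
mikey
miky
milos
mils
miltn
milton
mke
mkey
mlik
mlos
mlton
mrco
mrvin
mtt
mtthew
mtty
murice
nathan
nathn
ned
niklai
nikola
nikolai
nikoli
nils
nkolai
nls
norman
normn
nrman
nthan
omar
omr
orvill
orville
orvlle
oscar
oscr
pabl
pablo
paddy
pal
pat
patrck
patrick
pavel
pavl
pblo
pddy
percy
perre
pet
pete
peter
petey
petr
pety
philip
philp
phlip
pierr
pierre
piotr
pirre
pitr
potr
prcy
pte
pter
ptey
ptrick
pul
pvel
qentin
quentin
quentn
quntin
rajesh
rajsh
ralph
ralphe
ralphi
ralphie
rashd
rashid
raymnd
raymond
rbbie
rbert
rcardo
rch
rchard
rck
rcky
rdolfo
rfus
rger
ricard
ricardo
rich
richard
richrd
rick
ricky
ricrdo
rjesh
rlph
rlphie
rnald
rob
robbe
robbi
robbie
robert
robrt
rodlfo
rodolf
rodolfo
roger
rogr
ronald
ronld
roy
rshid
rssell
rufs
rufus
russell
russll
ryan
rymond
ryn
sam
samel
sammy
samuel
samul
samus
sanjay
sanjy
scott
sctt
seams
seamus
semus
serge
sergei
sergi
smmy
smuel
snjay
srgei
stefan
stefn
steph
stephn
stev
steve
steven
stevi
stevie
stevn
stfan
stph
stphen
stve
stven
stvie
sven
svn
sylvester
sylvestr
sylvster
tariq
tarq
tddy
ted
teddy
thedore
theo
theodor
theodore
theodre
thmas
tho
thodore
thomas
thoms
timmy
timothy
timthy
tmas
tmmy
tmothy
tny
tom
tomas
tommy
toms
triq
tyrne
tyron
tyrone
ulysses
ulysss
viktor
viktr
vinc
vince
vincent
vincnt
vinny
virgil
virgl
vktor
vladimir
vladimr
vladmir
vldimir
vnce
vncent
vnny
vrgil
wallac
wallace
wallce
walter
waltr
wei
wendell
wendll
wilbr
wilbur
willam
wille
willi
william
willie
willim
wlbur
wll
wllace
wlliam
wllie
wlter
wndell
ysuf
yusf
yusuf
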