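_
e
n
i
n_
r
d
en
s
a
t
h
en_
m
er
l
_d
g
e_
de
u
c
o
te
ie
r_
ch
nd
_s
in
t_
ei
f
ge
er_
_m
_e
b
d_
_de
den
den_
nd_
ne
s_
un
w
_a
_w
di
es
ie_
_di
der
h_
se
und
_die
_g
_u
an
ch_
die
ein
k
re
_die_
_ei
_f
_i
der_
die_
gen
hr
me
st
ten
ten_
_ein
_ge
_h
_un
_und
_und_
he
nn
und_
z
ä
_b
_der
_der_
_si
_v
eh
end
it
li
on
si
v
_den
_den_
_l
_n
al
am
as
be
eine
ine
le
m_
ma
mi
nde
nen
sc
sch
sen
te_
_al
_da
_das
_fr
_k
_ma
_mi
ag
an_
at
da
das
fe
fr
hre
ic
ich
in_
it_
man
nen_
nt
or
p
rt
sa
ste
_eine
_in
_in_
_man
_me
_mit
_vo
ar
as_
el
em
ert
es_
eu
g_
gen_
ich_
ig
is
ke
lie
ll
lt
men
mit
nden
nden_
ng
oc
och
on_
ra
ri
sen_
ss
ta
ter
ut
vo
we
zu
_an
_das_
_fe
_fre
_freu
_ih
_ihr
_ihre
_j
_le
_man_
_mit_
_r
_sc
_sch
_se
_sic
_sich
_st
_ve
_ver
_wa
_we
_z
ac
ach
ah
am_
bei
che
ck
cke
das_
eb
ehr
ehr_
eine_
einen
eis
eit
em_
end_
ende
enden
enn
ern
ese
fre
freu
hen
hen_
hl
ho
hr_
hren
ht
ht_
ih
ihr
ihre
ine_
inen
inen_
j
l_
man_
men_
mit_
mm
mme
mo
na
ne_
ni
nn_
nne
nte
ren
reu
rg
rge
rie
rn
sic
sich
sich_
sten
sten_
ter_
tt
tte
ute
ve
ver
wa
ö
_all
_als
_als_
_am
_am_
_an_
_be
_br
_dass
_eini
_er
_es
_geh
_ha
_hat
_hatt
_je
_jed
_jede
_ka
_meh
_mehr
_mo
_mor
_morg
_na
_nac
_nach
_no
_noc
_noch
_o
_p
_re
_rei
_reis
_sa
_sei
_sie
_sie_
_sin
_sind
_so
_sta
_stad
_um
_von
_von_
_vor
_war
_war_
_wen
_wenn
_wi
_wo
_woc
_woch
_zu
ab
ach_
ad
adt
adt_
agt
all
als
als_
ang
ar_
ass
ass_
ate
aten
aten_
att
atte
au
b_
ba
ben
br
che_
chl
chs
cht
cht_
cke_
dass
dass_
dert
des
des_
din
dt
dt_
ec
ed
ede
eg
ege
egen
egend
eini
einig
eise
eisen
eit_
ell
ene
enn_
ens
era
erat
ern_
erte
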