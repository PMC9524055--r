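à
au
aux
avec
ce
ces
dans
de
des
du
elle
en
est
et
eux
il
ils
je
la
le
les
leur
lui
ma
mais
me
même
mes
moi
mon
ne
nos
notre
nous
on
ou
où
par
pas
plus
pour
qu
que
qui
sa
se
ses
son
sont
sur
ta
te
tes
toi
ton
tu
un
une
vos
votre
vous
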