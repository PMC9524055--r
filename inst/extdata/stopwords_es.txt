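a
al
algo
como
con
cuando
de
del
desde
donde
el
ella
ellos
en
entre
era
es
esta
este
esto
fue
ha
hay
la
las
le
lo
los
más
mi
muy
nada
ni
no
nos
nosotros
o
para
pero
por
que
se
ser
si
sin
sobre
son
su
sus
también
te
tiene
todo
tu
un
una
uno
y
ya
yo
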