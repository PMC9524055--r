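alerta
casos
como
confinamento
confirmados
contra
cólera
dengue
doença
ebola
epidemia
este
febre
gripe
hospital
malária
medidas
mortes
novos
pacientes
pandemia
para
pessoas
peste
positivos
primeiros
pólio
quarentena
raiva
resposta
sarampo
saúde
segundo
sintomas
situação
surto
testes
vacina
vigilância
vírus
óbitos
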