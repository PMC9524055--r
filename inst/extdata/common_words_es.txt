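alerta
brote
casos
como
confinamiento
confirmados
contagios
contra
cuarentena
cólera
dengue
ebola
enfermedad
epidemia
este
fallecidos
fiebre
gripe
hospital
medidas
muertes
nuevos
pacientes
paludismo
pandemia
para
pero
peste
polio
positivos
primeros
pruebas
rabia
respuesta
salud
sanitaria
sarampión
según
situación
síntomas
vacuna
vigilancia
virus
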