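about
after
alert
all
and
are
breaking
can
cases
cholera
cluster
confirmed
contact
coronavirus
could
covid
daily
deaths
dengue
disease
doctors
ebola
epidemic
fever
first
flu
hantavirus
health
hospital
infection
influenza
latest
listeria
lockdown
malaria
measles
measures
monitoring
more
negative
news
officials
outbreak
pandemic
patients
people
plague
polio
positive
public
quarantine
rabies
report
reported
response
risk
salmonella
spread
surveillance
symptoms
testing
that
the
this
today
tracing
update
vaccine
virus
warning
with
workers
zika
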