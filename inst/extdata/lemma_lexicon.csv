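surface,lemma,pos
vaccines,vaccine,noun
vaccine,vaccine,noun
vaccination,vaccination,noun
vaccinations,vaccination,noun
vaccinated,vaccinate,verb
vaccinating,vaccinate,verb
vaccinate,vaccinate,verb
viruses,virus,noun
virus,virus,noun
infections,infection,noun
infection,infection,noun
infected,infect,verb
infecting,infect,verb
masks,mask,noun
mask,mask,noun
masked,mask,verb
lockdowns,lockdown,noun
lockdown,lockdown,noun
quarantines,quarantine,noun
quarantine,quarantine,noun
quarantined,quarantine,verb
hospitals,hospital,noun
hospital,hospital,noun
hospitalized,hospitalize,verb
deaths,death,noun
death,death,noun
died,die,verb
dying,die,verb
dies,die,verb
cases,case,noun
case,case,noun
tests,test,noun
test,test,noun
tested,test,verb
testing,testing,noun
doses,dose,noun
dose,dose,noun
dosed,dose,verb
variants,variant,noun
variant,variant,noun
economies,economy,noun
economy,economy,noun
economic,economic,adjective
jobs,job,noun
job,job,noun
unemployed,unemployed,adjective
unemployment,unemployment,noun
workers,worker,noun
worker,worker,noun
working,work,verb
worked,work,verb
works,work,verb
work,work,verb
governments,government,noun
government,government,noun
governmental,governmental,adjective
restrictions,restriction,noun
restriction,restriction,noun
restricted,restrict,verb
policies,policy,noun
policy,policy,noun
measures,measure,noun
measure,measure,noun
announced,announce,verb
announces,announce,verb
announcement,announcement,noun
announcements,announcement,noun
recovered,recover,verb
recovering,recover,verb
recovery,recovery,noun
treatments,treatment,noun
treatment,treatment,noun
treated,treat,verb
cures,cure,noun
cure,cure,noun
cured,cure,verb
conspiracies,conspiracy,noun
conspiracy,conspiracy,noun
theories,theory,noun
theory,theory,noun
stocks,stock,noun
stock,stock,noun
stocking,stock,verb
stocked,stock,verb
spreading,spread,verb
spreads,spread,verb
spread,spread,verb
quickly,quickly,adverb
slowly,slowly,adverb
really,really,adverb
very,very,adverb
new,new,adjective
safe,safe,adjective
safer,safe,adjective
safest,safe,adjective
effective,effective,adjective
deadly,deadly,adjective
global,global,adjective
positive,positive,adjective
negative,negative,adjective
better,good,adjective
worse,bad,adjective
staying,stay,verb
stayed,stay,verb
stays,stay,verb
stay,stay,verb
home,home,noun
homes,home,noun
distancing,distancing,noun
distance,distance,noun
schools,school,noun
school,school,noun
closed,close,verb
closures,closure,noun
closure,closure,noun
travels,travel,noun
travel,travel,noun
traveled,travel,verb
borders,border,noun
border,border,noun
numbers,number,noun
number,number,noun
rates,rate,noun
rate,rate,noun
immunity,immunity,noun
immune,immune,adjective
boosters,booster,noun
booster,booster,noun
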