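word	score
rape	1.40
murder	1.50
death	1.50
terrorist	1.60
suicide	1.70
die	1.70
killing	1.80
war	1.80
kill	1.90
dead	1.90
shooting	1.90
cancer	2.00
abuse	2.10
violence	2.10
tragedy	2.20
depressed	2.20
suffering	2.20
depression	2.30
hate	2.30
hopeless	2.30
worthless	2.30
grief	2.40
trauma	2.40
cruel	2.40
sad	2.40
pain	2.50
hurt	2.60
horrible	2.60
failure	2.70
terrible	2.70
shame	2.70
crisis	2.70
fear	2.70
lonely	2.80
anxiety	2.80
ashamed	2.80
victim	2.80
threat	2.80
afraid	2.90
panic	2.90
crying	2.90
angry	2.90
scared	2.90
danger	2.90
disease	2.90
awful	2.80
loss	3.00
shocked	3.00
broken	3.00
stress	3.00
stressed	3.00
illness	3.00
sick	3.10
stigma	3.10
struggling	3.10
worried	3.10
disorder	3.20
struggle	3.20
alone	3.20
guns	3.20
gun	3.30
tired	3.30
insane	3.40
wrong	3.40
problems	3.40
no	3.50
problem	3.50
vulnerable	3.50
crazy	3.60
never	3.70
taboo	3.70
issues	3.90
not	4.00
weird	4.00
issue	4.10
hospital	4.30
but	4.50
mental	4.60
government	4.60
treatment	4.90
or	4.90
the	4.98
of	5.00
to	5.00
in	5.00
that	5.00
on	5.00
at	5.00
by	5.00
an	5.00
media	5.00
a	5.10
is	5.10
it	5.10
this	5.10
school	5.10
therapist	5.10
and	5.20
be	5.20
therapy	5.20
doctor	5.20
with	5.30
work	5.30
news	5.30
public	5.30
medicine	5.30
for	5.40
men	5.40
services	5.40
change	5.50
people	5.50
man	5.50
campaign	5.50
person	5.60
week	5.60
woman	5.70
women	5.70
job	5.70
talking	5.70
talk	5.80
research	5.80
students	5.80
year	5.80
night	5.80
matter	5.90
conversation	5.90
world	5.90
student	5.90
social	5.90
program	5.90
time	5.90
programs	6.00
matters	6.00
story	6.00
today	6.00
awareness	6.10
mind	6.20
money	6.20
okay	6.20
day	6.20
listen	6.30
important	6.40
community	6.40
kid	6.40
help	6.50
open	6.50
kids	6.50
care	6.60
fine	6.60
listening	6.60
donation	6.70
support	6.80
well	6.80
donate	6.90
calm	6.90
share	6.90
sharing	6.90
living	6.90
caring	7.00
strong	7.00
helping	7.00
supportive	7.00
safe	7.00
rest	7.00
live	7.00
health	7.20
strength	7.20
praise	7.20
better	7.20
sleep	7.20
life	7.20
together	7.20
brave	7.30
hopeful	7.30
appreciate	7.30
hope	7.40
courage	7.40
kind	7.40
heart	7.40
appreciation	7.40
thanks	7.40
thank	7.50
good	7.50
proud	7.60
friend	7.60
party	7.60
gift	7.60
excited	7.70
best	7.70
friends	7.70
successful	7.70
family	7.70
great	7.80
success	7.80
grateful	7.80
free	7.80
winning	7.80
awesome	7.90
win	7.90
peace	7.90
celebrate	7.90
healthy	7.90
hug	7.90
kindness	8.00
fun	8.00
music	8.00
smiles	8.00
hugs	8.00
smile	8.10
amazing	8.10
beautiful	8.10
sunshine	8.10
loved	8.10
joy	8.20
laugh	8.20
happy	8.30
loving	8.30
love	8.40
happiness	8.40
wonderful	8.40
laughter	8.50
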