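word,count
the,100000
be,50000
to,33333
of,25000
and,20000
a,16666
in,14285
that,12500
have,11111
i,10000
it,9090
for,8333
not,7692
on,7142
with,6666
he,6250
as,5882
you,5555
do,5263
at,5000
this,4761
but,4545
his,4347
by,4166
from,4000
they,3846
we,3703
say,3571
her,3448
she,3333
or,3225
an,3125
will,3030
my,2941
one,2857
all,2777
would,2702
there,2631
their,2564
what,2500
so,2439
up,2380
out,2325
if,2272
about,2222
who,2173
get,2127
which,2083
go,2040
me,2000
when,1960
make,1923
can,1886
like,1851
time,1818
no,1785
just,1754
him,1724
know,1694
take,1666
people,1639
into,1612
year,1587
your,1562
good,1538
some,1515
could,1492
them,1470
see,1449
other,1428
than,1408
then,1388
now,1369
look,1351
only,1333
come,1315
its,1298
over,1282
think,1265
also,1250
back,1234
after,1219
use,1204
two,1190
how,1176
our,1162
work,1149
first,1136
well,1123
way,1111
even,1098
new,1086
want,1075
because,1063
any,1052
these,1041
give,1030
day,1020
most,1010
us,1000
is,990
was,980
are,970
has,961
had,952
were,943
been,934
being,925
am,917
does,909
did,900
done,892
said,884
says,877
made,869
went,862
gone,854
goes,847
came,840
took,833
taken,826
seen,819
knew,813
known,806
got,800
gotten,793
thought,787
looked,781
used,775
found,769
gave,763
given,757
told,751
asked,746
felt,740
became,735
left,729
put,724
meant,719
kept,714
let,709
begun,704
began,699
seemed,694
helped,689
talked,684
turned,680
started,675
showed,671
heard,666
played,662
ran,657
moved,653
lived,649
believed,645
brought,641
happened,636
wrote,632
written,628
provided,625
sat,621
stood,617
lost,613
paid,609
met,606
included,602
continued,598
set,595
learned,591
changed,588
led,584
understood,581
watched,578
followed,574
stopped,571
created,568
spoken,564
read,561
allowed,558
added,555
spent,552
grew,549
opened,546
walked,543
won,540
offered,537
remembered,534
loved,531
considered,529
appeared,526
bought,523
waited,520
served,518
died,515
sent,512
expected,510
built,507
stayed,505
fell,502
reached,500
killed,497
remained,495
suggested,492
raised,490
passed,487
sold,485
required,483
reported,480
decided,478
pulled,476
birch,473
canoe,471
slid,469
smooth,467
planks,465
glue,462
sheet,460
dark,458
blue,456
background,454
bright,452
sun,450
rise,448
box,446
thrown,444
beside,442
parked,440
truck,438
hogs,436
fed,434
chopped,432
corn,431
garbage,429
four,427
hours,425
steady,423
faced,421
large,420
size,418
stockings,416
hard,414
sell,413
salt,411
breeze,409
across,408
sea,406
girl,404
booth,403
fifty,401
bonds,400
small,398
pup,396
gnawed,395
hole,393
sock,392
fish,390
twisted,389
bent,387
hook,386
press,384
pants,383
sew,381
button,380
vest,378
swan,377
dive,375
far,374
short,373
basket,371
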