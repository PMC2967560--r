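mean:
        602.100674761459,604.394054040313,124.633444240317,294.600924244151,577.609919011593,630.979274399579,512.015897547826,505.023914156482,534.035353455693,557.2494356893
sd:
        173.58389752917,165.941738663241,22.2898306790739,140.737671777606,179.497652873397,55.9465107508004,45.6403762567788,3.0659785028547,25.7963117212057,18.6763857025653
count: 62500
k1: 5
k2: 7
s: 0.004

mean:
        599.731565685943,910.147710936144,560.424553928897,755.704769166186,379.171891137958,373.280976898968,170.290642883629,453.307323623449,258.413960458711,336.265952326357
sd:
        177.916606934741,40.3892597649246,115.837208554149,41.5264059789479,56.2937584705651,157.256240816787,34.6038698684424,114.149503642693,83.8565926533192,53.5244330298156
count: 62500
k1: 5
k2: 9
s: 0.004

mean:
        229.324695421383,212.998440722004,877.100905869156,993.221963290125,844.247019849718,910.436549223959,471.26973234117,224.418408004567,127.81465658918,279.683512402698
sd:
        163.221212057397,11.5225985646248,160.565849905834,20.8775670733303,153.321203729138,60.9621132723987,153.85748418048,108.131145266816,72.4741064477712,18.5113832354546
count: 62500
k1: 5
k2: 7
s: 0.004

mean:
        549.480673857033,163.719896925613,164.596953662112,786.332777468488,751.113419653848,784.214704297483,654.354914557189,378.10439732857,8.56696744449437,955.329553689808
sd:
        167.72322957404,42.6849875133485,98.9427112508565,127.248851256445,184.218278620392,2.34880815260112,53.4805834293365,87.1144203469157,165.893418947235,174.188807699829
count: 62500
k1: 6
k2: 8
s: 0.004

mean:
        184.282035101205,679.977399529889,766.337673645467,682.13222711347,209.130792180076,711.943760979921,605.298185488209,340.559205040336,41.1703209392726,401.752509409562
sd:
        15.8119291067123,62.5105300918221,65.0151871610433,15.6732914503664,30.0439541228116,30.4850139189512,182.684720214456,140.45057981275,164.109664410353,133.112618140876
count: 62500
k1: 7
k2: 6
s: 0.004

mean:
        822.188047459349,820.741926785558,199.944551801309,601.135490695015,429.83600194566,637.568331789225,420.024005230516,879.870038945228,320.728030521423,315.312843769789
sd:
        98.7144168931991,67.5340591464192,44.557198882103,166.047933744267,107.699356786907,19.7395789902657,21.9180284999311,114.771006209776,107.597032608464,97.5009956862777
count: 62500
k1: 8
k2: 4
s: 0.004

mean:
        861.575354356319,847.129042958841,267.273619538173,605.403405148536,830.954045988619,591.66346443817,198.839682852849,772.646997589618,125.125238206238,888.210923643783
sd:
        61.8693524040282,129.854591889307,52.4788772221655,32.3126781731844,21.1013926658779,87.536078505218,7.7041492331773,191.735394857824,101.548426924273,72.4614560138434
count: 62500
k1: 10
k2: 7
s: 0.004

mean:
        759.509253315628,889.600470429286,180.350180482492,786.488520447165,547.374699730426,497.445829445496,108.780974522233,586.733639473096,897.322560893372,187.683837953955
sd:
        105.994560755789,133.988927211612,156.585254659876,37.5407543499023,113.280171900988,39.3205593340099,61.4819021895528,32.2176888585091,19.6638920344412,51.5125409699976
count: 62500
k1: 6
k2: 10
s: 0.004
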