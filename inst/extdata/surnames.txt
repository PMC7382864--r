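SILVA
SANTOS
OLIVEIRA
SOUZA
RODRIGUES
FERREIRA
ALVES
PEREIRA
LIMA
GOMES
COSTA
RIBEIRO
MARTINS
CARVALHO
ALMEIDA
LOPES
SOARES
FERNANDES
VIEIRA
BARBOSA
ROCHA
DIAS
NASCIMENTO
ANDRADE
MOREIRA
NUNES
MARQUES
MACHADO
MENDES
FREITAS
CARDOSO
RAMOS
GONCALVES
SANTANA
TEIXEIRA
ARAUJO
PINTO
CORREIA
MONTEIRO
CAVALCANTI
MOURA
BATISTA
BORGES
REIS
CAMPOS
DUARTE
MELO
NOGUEIRA
BARROS
CASTRO
MIRANDA
AZEVEDO
CUNHA
QUEIROZ
FARIAS
MOTA
MEDEIROS
GARCIA
MORAES
TAVARES
AGUIAR
BRITO
SALES
XAVIER
SERRA
MAGALHAES
SAMPAIO
ASSIS
BEZERRA
GUIMARAES
PAIVA
MACEDO
SIQUEIRA
ANTUNES
BRANDAO
CALDAS
CAMARA
CAMARGO
CARNEIRO
CASSIANO
CHAVES
COELHO
CORDEIRO
COUTINHO
CRUZ
DANTAS
DOMINGUES
DORNELES
DUTRA
ESTEVES
FALCAO
FEITOSA
FIGUEIREDO
FONSECA
FONTES
FRAGA
FRANCA
FURTADO
GALVAO
GENTIL
GODOY
GUEDES
HOLANDA
JESUS
LACERDA
LEAL
LEITE
LESSA
LINHARES
LUCENA
MAIA
MARINHO
MATOS
MENEZES
MESQUITA
MILANEZ
MONTENEGRO
MORAIS
NEGREIROS
NEVES
NOBREGA
OTONI
PACHECO
PADILHA
PAES
PANTOJA
PASSOS
PEDROSA
PEIXOTO
PENA
PESSOA
PIMENTA
PIMENTEL
PINHEIRO
PIRES
PONTES
PORTELA
PRADO
QUADROS
RANGEL
REGO
RESENDE
REZENDE
RIOS
ROSA
SALDANHA
SALGADO
SANCHES
SARAIVA
SARMENTO
SEABRA
SEVERO
SIMAO
SIMOES
SODRE
TELES
TERRA
TOLEDO
TORRES
TRINDADE
VALENTE
VALVERDE
VARELA
VASCONCELOS
VAZ
VELOSO
VERAS
VIANA
VILELA
ABREU
AMARAL
AMORIM
ARANTES
ARRUDA
AVELAR
BANDEIRA
BARCELOS
BARRETO
BASTOS
BELMONTE
BENTO
BITTENCOURT
BONFIM
BRAGA
BRASIL
BUENO
CABRAL
CANDIDO
CAPISTRANO
CASTILHO
CAVALCANTE
CERQUEIRA
COUTO
CRISPIM
DOURADO
EVANGELISTA
FIGUEIRA
FERRAZ
FERREIRA
FIALHO
FLORES
FOGACA
FORTES
FREIRE
GALINDO
GAMA
GASPAR
GOUVEIA
GUERRA
LEMOS
LUZ
MALTA
MATTOS
MAURICIO
MEIRELES
MELLO
MODESTO
MONTES
MORENO
MOTTA
NAVARRO
OLIVA
ORNELAS
PAULA
PRATES
QUINTANA
RAPOSO
SANTIAGO
SERPA
TABORDA
URBANO
VALE
VENTURA
VILAR
ZAGO
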